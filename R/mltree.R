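# Desk-scale maximum-likelihood tree inference: ML pairwise distances,
# neighbor-joining start tree, per-branch 1D optimization sweeps and an
# NNI topology search.

BL_MIN <- 1e-8
BL_MAX <- 20

#' Maximum-likelihood pairwise distances
#'
#' For every sequence pair, counts the k x k state-pair matrix over
#' columns where both rows have a known state and maximizes
#' \eqn{\sum N_{ij} \log(\pi_i P_{ij}(t))} over the branch length t.
#'
#' @param msa an [AlignmentBlock-class]
#' @param model a [SubstitutionModel-class]
#' @return symmetric distance matrix (substitutions/site)
#' @export
mlPairwiseDistances <- function(msa, model) {
  rows <- alignmentRows(msa)
  ids <- names(rows)
  k <- length(model@states)
  idx <- lapply(rows, function(r) {
    i <- match(strsplit(r, "")[[1]], model@states)
    i
  })
  logpi <- log(model@freqs)
  D <- matrix(0, length(ids), length(ids),
              dimnames = list(ids, ids))
  for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
    ia <- idx[[a]]; ib <- idx[[b]]
    ok <- !is.na(ia) & !is.na(ib)
    N <- matrix(0, k, k)
    tab <- table(factor(ia[ok], levels = seq_len(k)),
                 factor(ib[ok], levels = seq_len(k)))
    N[] <- as.numeric(tab)
    f <- function(t) {
      P <- transitionProbability(model, t)
      sum(N * (log(pmax(P, 1e-300)) + logpi))
    }
    d <- optimize(f, c(BL_MIN, BL_MAX), maximum = TRUE)$maximum
    # identical sequences: the optimum sits at the lower bound
    if (sum(N) > 0 && sum(diag(N)) == sum(N)) d <- BL_MIN
    D[a, b] <- D[b, a] <- d
  }
  D
}

#' Neighbor-joining start tree
#'
#' Neighbor-joining with negative branch lengths clamped to zero.  The
#' three-taxon case uses the closed-form three-point formulas.
#'
#' @param D symmetric non-negative distance matrix with taxon names
#' @return unrooted ape `phylo`
#' @export
njStartTree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distances must be non-negative")
  ids <- rownames(D)
  if (nrow(D) == 3L) {
    a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    txt <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);", ids[1], max(a, 0),
                   ids[2], max(b, 0), ids[3], max(c3, 0))
    return(ape::read.tree(text = txt))
  }
  phy <- ape::nj(D)
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

# One sweep of per-branch 1D optimization.  Inside (down) partials are
# cached for the whole sweep; outside partials are rebuilt along a
# preorder traversal using the lengths already updated in this sweep,
# so sibling and ancestor updates feed into each branch immediately.
branch_sweep <- function(td, model, lens, tol) {
  k <- length(model@states)
  P <- build_P_cube(model, lens, length(td$children))
  L <- cpp_down_partials(td$children, td$postorder, P, td$patterns, k)
  w <- td$weights
  n_pat <- nrow(td$patterns)
  B <- vector("list", length(td$children))
  B[[td$root]] <- matrix(model@freqs, nrow = k, ncol = n_pat)
  for (u in rev(td$postorder)) {        # parents before children
    ch <- td$children[[u]]
    for (v in ch) {
      acc <- B[[u]]
      for (s in ch) if (s != v) acc <- acc * (P[, , s] %*% L[, , s])
      Lv <- L[, , v]
      f <- function(t) {
        site <- colSums(acc * (transitionProbability(model, t) %*% Lv))
        sum(w * log(pmax(site, 1e-300)))
      }
      opt <- optimize(f, c(BL_MIN, BL_MAX), maximum = TRUE,
                      tol = max(tol * 1e-2, 1e-8))
      lens[v] <- opt$maximum
      P[, , v] <- transitionProbability(model, lens[v])
      if (length(td$children[[v]]) > 0L)
        B[[v]] <- crossprod(P[, , v], acc)
    }
  }
  lens
}

#' Optimize branch lengths by coordinate sweeps
#'
#' Each sweep performs a bracketed 1D optimization per branch (inside
#' and outside partial likelihoods cached per sweep); sweeps repeat
#' until the log-likelihood improvement drops below `tol`.  The
#' log-likelihood is non-decreasing across accepted sweeps: a sweep
#' that fails to improve is rejected.
#'
#' @param phy ape `phylo` with starting branch lengths
#' @param msa an [AlignmentBlock-class]
#' @param model a [SubstitutionModel-class]
#' @param tol log-likelihood convergence tolerance (default 1e-4)
#' @param max_sweeps maximum sweeps (default 20)
#' @return `phy` with optimized `edge.length`; the final log-likelihood
#'   is attached as attribute "logLik"
#' @export
optimizeBranchLengths <- function(phy, msa, model, tol = 1e-4,
                                  max_sweeps = 20) {
  td <- tree_data(phy, msa, model)
  lens <- lengths_by_node(phy)
  lens[!is.na(lens)] <- pmin(pmax(lens[!is.na(lens)], BL_MIN), BL_MAX)
  ll <- tree_loglik_for_lens(td, model, lens)
  for (sweep in seq_len(max_sweeps)) {
    cand <- branch_sweep(td, model, lens, tol)
    ll_new <- tree_loglik_for_lens(td, model, cand)
    if (ll_new < ll) break          # reject non-improving sweep
    improved <- ll_new - ll
    lens <- cand
    ll <- ll_new
    if (improved < tol) break
  }
  out <- set_lengths_by_node(phy, lens)
  attr(out, "logLik") <- ll
  out
}

tree_loglik_for_lens <- function(td, model, lens) {
  P <- build_P_cube(model, lens, length(td$children))
  cpp_tree_loglik(td$children, td$postorder, P, td$patterns,
                  model@freqs, td$weights, td$root)
}

# the two NNI rearrangements around an internal edge (u, v):
# exchange one non-v neighbor subtree of u with one child subtree of v
nni_alternatives <- function(phy, edge_row) {
  u <- phy$edge[edge_row, 1]
  v <- phy$edge[edge_row, 2]
  n_tip <- length(phy$tip.label)
  if (v <= n_tip) return(list())
  ch_v <- phy$edge[phy$edge[, 1] == v, 2]
  ch_u <- setdiff(phy$edge[phy$edge[, 1] == u, 2], v)
  if (length(ch_u) == 0L || length(ch_v) < 2L) return(list())
  w <- ch_u[1]
  lapply(ch_v[1:2], function(cswap) {
    e2 <- phy$edge
    e2[e2[, 1] == u & e2[, 2] == w, 2] <- cswap
    e2[e2[, 1] == v & e2[, 2] == cswap, 2] <- w
    phy2 <- phy
    phy2$edge <- e2
    phy2
  })
}

#' Nearest-neighbor-interchange topology search
#'
#' Evaluates both NNI alternatives around every internal edge, accepts
#' the best strictly improving move (followed by one branch-length
#' sweep), and repeats until no move improves the log-likelihood or
#' `max_rounds` is reached.
#'
#' @param phy starting tree with branch lengths
#' @param msa an [AlignmentBlock-class]
#' @param model a [SubstitutionModel-class]
#' @param max_rounds maximum accepted moves (default 10)
#' @param resweep run one branch-length sweep after each accepted move
#' @return tree with attribute "logLik"
#' @export
nniSearch <- function(phy, msa, model, max_rounds = 10,
                      resweep = TRUE) {
  cur <- phy
  # site patterns depend only on the alignment: compress once and
  # rebuild only the topology-dependent pieces per candidate tree
  pat <- site_patterns(msa, phy$tip.label, model@states)
  ll_topo <- function(tr) {
    td <- list(children = phylo_children(tr),
               postorder = phylo_postorder(tr),
               root = length(tr$tip.label) + 1L,
               patterns = pat$states, weights = pat$weights)
    tree_loglik_for_lens(td, model, lengths_by_node(tr))
  }
  ll <- ll_topo(cur)
  n_tip <- length(phy$tip.label)
  for (round in seq_len(max_rounds)) {
    best <- NULL
    best_ll <- ll
    internal <- which(cur$edge[, 2] > n_tip)
    for (er in internal) {
      for (alt in nni_alternatives(cur, er)) {
        ll_alt <- ll_topo(alt)
        if (ll_alt > best_ll + 1e-9) {
          best <- alt
          best_ll <- ll_alt
        }
      }
    }
    if (is.null(best)) break
    cur <- best
    if (resweep) {
      cur <- optimizeBranchLengths(cur, msa, model, max_sweeps = 1)
      best_ll <- attr(cur, "logLik")
    }
    ll <- best_ll
  }
  attr(cur, "logLik") <- ll
  cur
}

#' Full maximum-likelihood tree inference
#'
#' ML pairwise distances -> neighbor-joining start tree -> branch-length
#' optimization -> NNI search.
#'
#' @inheritParams optimizeBranchLengths
#' @param nni_rounds maximum NNI moves (default 10)
#' @return unrooted ML tree with attribute "logLik"
#' @export
mlTree <- function(msa, model, tol = 1e-4, nni_rounds = 10) {
  D <- mlPairwiseDistances(msa, model)
  phy <- njStartTree(D)
  phy <- optimizeBranchLengths(phy, msa, model, tol = tol)
  nniSearch(phy, msa, model, max_rounds = nni_rounds)
}
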