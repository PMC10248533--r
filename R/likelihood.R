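# Felsenstein pruning over ape `phylo` trees.
#
# Internal layout: nodes follow ape numbering (tips 1..n, internals
# n+1..).  The branch "above" node v is the edge whose child is v, so
# branch lengths are stored per node.  Alignment columns are compressed
# to unique site patterns with weights; gaps and unknown residues are
# missing data (partial-likelihood vector of ones).

# compress msa rows (for the given tips) into a pattern matrix
# n_pat x n_tip of state indices (0 = missing) plus pattern weights
site_patterns <- function(msa, tips, states) {
  rows <- alignmentRows(msa)
  missing_rows <- setdiff(tips, names(rows))
  if (length(missing_rows))
    stop("leaf without alignment row: ",
         paste(missing_rows, collapse = ", "))
  m <- do.call(rbind, strsplit(rows[tips], ""))   # n_tip x width
  idx <- match(m, states)
  idx[is.na(idx)] <- 0L
  dim(idx) <- dim(m)
  keys <- apply(idx, 2, paste, collapse = ",")
  first <- !duplicated(keys)
  weights <- as.numeric(table(factor(keys, levels = keys[first])))
  list(states = t(idx[, first, drop = FALSE]),   # n_pat x n_tip
       weights = weights)
}

phylo_children <- function(phy) {
  n_node <- length(phy$tip.label) + phy$Nnode
  ch <- vector("list", n_node)
  for (i in seq_len(n_node)) ch[[i]] <- integer()
  for (r in seq_len(nrow(phy$edge)))
    ch[[phy$edge[r, 1]]] <- c(ch[[phy$edge[r, 1]]], phy$edge[r, 2])
  ch
}

# internal nodes in postorder (children before parents)
phylo_postorder <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  unique(po$edge[, 1])
}

# branch length above each node (NA for the root)
lengths_by_node <- function(phy) {
  n_node <- length(phy$tip.label) + phy$Nnode
  out <- rep(NA_real_, n_node)
  out[phy$edge[, 2]] <- phy$edge.length
  out
}

set_lengths_by_node <- function(phy, lens) {
  phy$edge.length <- lens[phy$edge[, 2]]
  phy
}

build_P_cube <- function(model, lens, n_node) {
  k <- length(model@states)
  P <- array(0, dim = c(k, k, n_node))
  for (v in seq_len(n_node)) {
    P[, , v] <- if (is.na(lens[v])) diag(k)
                else transitionProbability(model, lens[v])
  }
  P
}

# bundle everything the C++ kernels need
tree_data <- function(phy, msa, model) {
  if (is.null(phy$edge.length))
    stop("tree must have branch lengths")
  pat <- site_patterns(msa, phy$tip.label, model@states)
  list(children = phylo_children(phy),
       postorder = phylo_postorder(phy),
       root = length(phy$tip.label) + 1L,
       patterns = pat$states, weights = pat$weights)
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Gap and unknown characters are treated as missing data; site
#' log-likelihoods are summed over alignment columns.  Rate
#' heterogeneity is off by default (the model strings this package
#' mirrors carry no gamma term); setting `gamma_shape` enables a
#' discrete-gamma mixture with `gamma_categories` equal-weight
#' categories (median discretisation), mean rate one.
#'
#' @param phy ape `phylo` with branch lengths; tip labels must all have
#'   rows in `msa`
#' @param msa an [AlignmentBlock-class]
#' @param model a [SubstitutionModel-class]
#' @param gamma_shape optional gamma shape alpha (NULL = uniform rates)
#' @param gamma_categories number of discrete categories (default 4)
#' @return log-likelihood (numeric scalar)
#' @export
treeLogLik <- function(phy, msa, model, gamma_shape = NULL,
                       gamma_categories = 4) {
  td <- tree_data(phy, msa, model)
  lens <- lengths_by_node(phy)
  if (is.null(gamma_shape)) {
    P <- build_P_cube(model, lens, length(td$children))
    return(cpp_tree_loglik(td$children, td$postorder, P, td$patterns,
                           model@freqs, td$weights, td$root))
  }
  rates <- discrete_gamma_rates(gamma_shape, gamma_categories)
  # per-pattern likelihood averaged over equal-weight rate categories
  per_cat <- vapply(rates, function(r) {
    P <- build_P_cube(model, lens * r, length(td$children))
    L <- cpp_down_partials(td$children, td$postorder, P, td$patterns,
                           length(model@states))
    as.numeric(model@freqs %*% L[, , td$root])
  }, numeric(nrow(td$patterns)))
  site <- rowMeans(matrix(per_cat, nrow = nrow(td$patterns)))
  sum(td$weights * log(pmax(site, 1e-300)))
}

# median discretisation of a mean-one gamma into k equal-weight
# categories, renormalised to mean exactly one
discrete_gamma_rates <- function(alpha, k = 4) {
  q <- stats::qgamma((2 * seq_len(k) - 1) / (2 * k), shape = alpha,
                     rate = alpha)
  q / mean(q)
}

# up ("outside") partial likelihoods: A[[v]](i, s) = likelihood of all
# data outside subtree(v) given state i at parent(v), including the
# root prior.  Site likelihood for the edge above v is then
# sum_i A_v(i,s) * [P(t_v) L_v](i,s).
up_partials <- function(td, P, L, pi) {
  A <- vector("list", length(td$children))
  B <- vector("list", length(td$children))  # outside lik given state AT v
  B[[td$root]] <- matrix(pi, nrow = length(pi), ncol = dim(L)[2])
  # reversed postorder visits parents before children, root first
  for (u in rev(td$postorder)) {
    ch <- td$children[[u]]
    if (length(ch) == 0L) next
    M <- lapply(ch, function(w) P[, , w] %*% L[, , w])
    for (ci in seq_along(ch)) {
      v <- ch[[ci]]
      acc <- B[[u]]
      for (cj in seq_along(ch)) if (cj != ci) acc <- acc * M[[cj]]
      A[[v]] <- acc
      if (length(td$children[[v]]) > 0L)
        B[[v]] <- crossprod(P[, , v], acc)
    }
  }
  A
}
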