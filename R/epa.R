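# Likelihood-based evolutionary placement of one query sequence onto a
# fixed reference tree: the query is attached by a pendant branch at
# every edge midpoint in turn, only the pendant length is optimized,
# and the per-edge log-likelihoods are reported.

#' Evolutionary placement of a query on a reference tree
#'
#' @param query_row gapped query row of width = reference alignment
#'   width (e.g. from [addKeepLength()]); a named character scalar or a
#'   list with elements `row` and optionally `id`
#' @param ref_tree reference ape `phylo` with optimized branch lengths
#' @param ref_msa reference [AlignmentBlock-class]
#' @param model a [SubstitutionModel-class]
#' @param query_id id recorded on the result
#' @return a [PlacementResult-class]
#' @export
epaPlace <- function(query_row, ref_tree, ref_msa, model,
                     query_id = "query") {
  if (is.list(query_row)) {
    if (!is.null(query_row$id)) query_id <- query_row$id
    query_row <- query_row$row
  }
  if (!is.null(names(query_row)) && nzchar(names(query_row)[1]))
    query_id <- names(query_row)[1]
  query_row <- as.character(query_row)
  if (nchar(query_row) != alignmentWidth(ref_msa))
    stop("query row width must equal the reference alignment width")
  qstates <- match(strsplit(query_row, "")[[1]], model@states)
  if (all(is.na(qstates))) stop("query is all gaps")

  td <- tree_data(ref_tree, ref_msa, model)
  lens <- lengths_by_node(ref_tree)
  k <- length(model@states)
  P <- build_P_cube(model, lens, length(td$children))
  # patterns must be compressed jointly with the query column states
  pat_full <- site_patterns_with_query(ref_msa, ref_tree$tip.label,
                                       model@states, qstates)
  td$patterns <- pat_full$ref_states
  w <- pat_full$weights
  L <- cpp_down_partials(td$children, td$postorder, P, td$patterns, k)
  A <- up_partials(td, P, L, model@freqs)
  Lq <- matrix(1, k, nrow(pat_full$ref_states))
  qs <- pat_full$query_states
  known <- which(!is.na(qs) & qs > 0)
  Lq[, known] <- 0
  Lq[cbind(qs[known], known)] <- 1

  n_edge <- nrow(ref_tree$edge)
  pend <- numeric(n_edge)
  ll <- numeric(n_edge)
  for (er in seq_len(n_edge)) {
    v <- ref_tree$edge[er, 2]
    half <- transitionProbability(model, lens[v] / 2)
    pre <- crossprod(half, A[[v]]) * (half %*% L[, , v])
    f <- function(p) {
      site <- colSums(pre * (transitionProbability(model, p) %*% Lq))
      sum(w * log(pmax(site, 1e-300)))
    }
    opt <- optimize(f, c(BL_MIN, BL_MAX), maximum = TRUE)
    # the optimum frequently sits at the lower bound for identical
    # sequences; compare against the bound explicitly
    ll_bound <- f(BL_MIN)
    if (ll_bound > opt$objective) {
      pend[er] <- BL_MIN
      ll[er] <- ll_bound
    } else {
      pend[er] <- opt$maximum
      ll[er] <- opt$objective
    }
  }
  best <- which.max(ll)
  new("PlacementResult", query = query_id, bestEdge = as.integer(best),
      pendantLength = pend[best], logLik = ll[best],
      edgeTable = data.frame(edge = seq_len(n_edge), pendant = pend,
                             logLik = ll))
}

# joint pattern compression of reference rows plus the query
site_patterns_with_query <- function(msa, tips, states, qstates) {
  rows <- alignmentRows(msa)
  m <- do.call(rbind, strsplit(rows[tips], ""))
  idx <- match(m, states)
  idx[is.na(idx)] <- 0L
  dim(idx) <- dim(m)
  q <- qstates
  q[is.na(q)] <- 0L
  keys <- paste(apply(idx, 2, paste, collapse = ","), q, sep = "|")
  first <- !duplicated(keys)
  weights <- as.numeric(table(factor(keys, levels = keys[first])))
  list(ref_states = t(idx[, first, drop = FALSE]),
       query_states = q[first], weights = weights)
}
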