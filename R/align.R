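# Seed-anchored progressive alignment and keep-length addition.
#
# The structural seed alignment anchors the column space: seed rows keep
# their mutual gap pattern, new sequences only ever insert shared new
# columns.  Column-residue scores are BLOSUM62 averaged over the
# column's residue composition (gaps contribute zero, which makes gappy
# columns cheap to skip).

# score matrix: alignment columns (rows) x query residues (cols),
# BLOSUM62 half-bit units
column_score_matrix <- function(aln_mat, residues) {
  n_rows <- nrow(aln_mat)
  B <- blosum62()
  Fm <- vapply(seq_len(ncol(aln_mat)), function(i) {
    tabulate(match(aln_mat[, i], AA20), 20L)
  }, numeric(20)) / n_rows                      # 20 x m
  chars <- strsplit(residues, "")[[1]]
  idx <- match(chars, AA20)
  S <- matrix(0, nrow = ncol(aln_mat), ncol = length(chars))
  known <- which(!is.na(idx))
  if (length(known))
    S[, known] <- t(Fm) %*% B[, idx[known], drop = FALSE]
  S
}

# align one ungapped query to an alignment; returns the DP path
align_query_to_alignment <- function(aln_mat, query,
                                     gap_open = 11, gap_extend = 1) {
  S <- column_score_matrix(aln_mat, query)
  cpp_affine_align(S, gap_open, gap_extend, 1L)$path
}

#' Progressively align sequences onto a seed alignment
#'
#' Sequences are added one at a time in order of decreasing profile
#' score to the seed.  Seed columns are never re-arranged; a query
#' residue that matches no existing column inserts a shared new column
#' (gap in all previous rows).
#'
#' @param seqs AAStringSet (or named character) of ungapped sequences
#' @param seed an [AlignmentBlock-class]; its rows are retained first in
#'   the output
#' @param gap_open,gap_extend affine gap penalties (BLOSUM62 half-bit
#'   units)
#' @return an [AlignmentBlock-class] of width >= the seed width
#' @export
alignToSeed <- function(seqs, seed, gap_open = 11, gap_extend = 1) {
  sq <- as_named_chr(seqs)
  if (length(sq) == 0L) return(seed)
  if (is.null(names(sq)) || anyDuplicated(names(sq)))
    stop("query ids must be unique")
  if (any(names(sq) %in% names(alignmentRows(seed))))
    stop("query ids collide with seed row ids")
  prof <- buildProfile(seed)
  guide <- vapply(sq, function(s)
    scoreSequence(prof, s, "local")$score, numeric(1))
  rows <- strsplit(alignmentRows(seed), "")
  for (qi in order(-guide)) {
    aln_mat <- do.call(rbind, rows)
    path <- align_query_to_alignment(aln_mat, sq[[qi]],
                                     gap_open, gap_extend)
    qchars <- strsplit(sq[[qi]], "")[[1]]
    m <- ncol(aln_mat)
    # new column layout: for every path step, an output column keyed by
    # the source alignment column (or 0 for an inserted column)
    src_col <- path[, 1]
    qrow <- ifelse(path[, 2] > 0, qchars[pmax(path[, 2], 1L)], "-")
    rows <- lapply(rows, function(r) {
      out <- rep("-", length(src_col))
      out[src_col > 0] <- r[src_col[src_col > 0]]
      out
    })
    rows[[length(rows) + 1L]] <- qrow
    names(rows)[length(rows)] <- names(sq)[qi]
  }
  out <- vapply(rows, paste, character(1), collapse = "")
  alignmentBlock(out)
}

#' Add a query to a fixed-width alignment (keep-length)
#'
#' The query is aligned to the alignment's column profile; residues
#' falling in insertions relative to the alignment are recorded and
#' excluded, so the alignment width never changes.
#'
#' @param msa an [AlignmentBlock-class]
#' @param query ungapped sequence (character or AAString)
#' @param gap_open,gap_extend affine gap penalties
#' @return list: `row` (gapped query string of width = msa width),
#'   `discarded` (1-based query positions dropped), `n_discarded`
#' @export
addKeepLength <- function(msa, query, gap_open = 11, gap_extend = 1) {
  query <- as.character(query)
  if (!nzchar(query)) stop("empty query")
  aln_mat <- as.matrix(msa)
  path <- align_query_to_alignment(aln_mat, query, gap_open,
                                   gap_extend)
  qchars <- strsplit(query, "")[[1]]
  row <- rep("-", alignmentWidth(msa))
  both <- path[, 1] > 0 & path[, 2] > 0
  row[path[both, 1]] <- qchars[path[both, 2]]
  discarded <- path[path[, 1] == 0, 2]
  list(row = paste(row, collapse = ""),
       discarded = as.integer(discarded),
       n_discarded = length(discarded))
}
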