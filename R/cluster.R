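# Greedy identity clustering with paired-half retention.
#
# Identity convention (fixed once, used everywhere): global alignment
# with BLOSUM62, gap open 11 / extend 1; identity = identical aligned
# pairs / aligned columns excluding double-gap columns, terminal gaps
# included.  A global pairwise alignment has no double-gap columns, so
# the denominator is the alignment length.

as_named_chr <- function(x) {
  if (is.character(x)) return(x)
  out <- as.character(x)
  if (is.null(names(out))) names(out) <- names(x)
  out
}

#' Pairwise sequence identity
#'
#' @param a,b sequences (character or AAString), nonempty
#' @return identity fraction in [0, 1]
#' @export
pairwiseIdentity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  if (a == b) return(1.0)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- !(p == "-" & s == "-")
  sum(p[keep] == s[keep] & p[keep] != "-") / sum(keep)
}

#' Greedy identity clustering into representatives
#'
#' Sequences are visited by decreasing length (ties broken by
#' lexicographic id); each joins the earliest-created representative it
#' matches at or above the identity threshold, otherwise it founds a new
#' cluster.  This emulates centroid-greedy clustering with identity as
#' the sole criterion.
#'
#' @param seqs AAStringSet (or named character vector)
#' @param threshold minimum identity fraction in (0, 1]
#' @param group free-text tag recorded on the result (e.g. "plants")
#' @return a [ClusterSet-class]
#' @export
greedyCluster <- function(seqs, threshold, group = "") {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  sq <- as_named_chr(seqs)
  ids <- names(sq)
  if (is.null(ids) || anyDuplicated(ids)) stop("ids must be unique")
  ord <- order(-nchar(sq), ids)
  clusters <- list()
  reps <- character()
  for (i in ord) {
    idents <- if (length(reps))
      identity_to_many(sq[[i]], sq[reps]) else numeric()
    hit <- which(idents >= threshold)
    if (length(hit)) {
      r <- reps[hit[1]]            # earliest-created representative
      clusters[[r]] <- c(clusters[[r]], ids[[i]])
    } else {
      reps <- c(reps, ids[[i]])
      clusters[[ids[[i]]]] <- ids[[i]]
    }
  }
  new("ClusterSet", clusters = clusters, threshold = threshold,
      group = group)
}

# identities of one sequence against many, one vectorized alignment
# call (same convention as pairwiseIdentity)
identity_to_many <- function(x, refs) {
  exact <- refs == x
  out <- as.numeric(exact)
  todo <- which(!exact)
  if (length(todo)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(refs[todo]), Biostrings::AAString(x),
      type = "global", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")
    out[todo] <- vapply(seq_along(todo), function(k) {
      keep <- !(p[[k]] == "-" & s[[k]] == "-")
      sum(p[[k]][keep] == s[[k]][keep] & p[[k]][keep] != "-") /
        sum(keep)
    }, numeric(1))
  }
  out
}

#' Verify a clustering post hoc
#'
#' Independently recomputes every member -> representative identity and
#' checks it reaches the cluster threshold.
#'
#' @param cs a [ClusterSet-class]
#' @param seqs the clustered sequences
#' @return TRUE, or a character vector describing violations
#' @export
verifyClusters <- function(cs, seqs) {
  sq <- as_named_chr(seqs)
  bad <- character()
  for (r in names(cs@clusters)) {
    for (m in cs@clusters[[r]]) {
      if (m == r) next
      idn <- pairwiseIdentity(sq[[m]], sq[[r]])
      if (idn < cs@threshold)
        bad <- c(bad, sprintf("%s -> %s: %.3f < %.3f", m, r, idn,
                              cs@threshold))
    }
  }
  if (length(bad)) bad else TRUE
}

#' Close a representative set under pseudodimer pairing
#'
#' Where one half of a pseudodimer is a representative, the other half
#' is kept as well.
#'
#' @param reps character vector of representative ids
#' @param pair_map named character vector mapping each pseudodimer half
#'   to its partner (must be symmetric)
#' @return character vector: the closure of `reps` under `pair_map`
#' @export
keepPairHalves <- function(reps, pair_map) {
  pair_map <- pair_map[!is.na(pair_map)]
  if (length(pair_map)) {
    back <- pair_map[pair_map]
    ok <- !is.na(back) & back == names(pair_map)
    if (!all(ok))
      stop("pair_map must be symmetric")
  }
  out <- unique(reps)
  repeat {
    add <- setdiff(unname(pair_map[intersect(out, names(pair_map))]),
                   out)
    if (length(add) == 0L) break
    out <- c(out, add)
  }
  out
}
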