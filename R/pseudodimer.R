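# Pseudodimer handling: a single polypeptide carrying two tandem
# Get3/ArsA domains is split into two monomer-equivalent halves midway
# between the end of the first domain and the start of the second.

#' Construct a DomainRecordSet
#'
#' @param seqs AAStringSet (or named character) of domain residues
#' @param parent parent protein id per record
#' @param start,end 1-based inclusive interval on the parent
#' @param provenance "single", "pseudodimer_N" or "pseudodimer_C"
#' @param partner partner record id (NA when unpaired)
#' @param has_acd logical alphaCD flag
#' @return a [DomainRecordSet-class]
#' @export
domainRecordSet <- function(seqs, parent, start, end,
                            provenance = "single",
                            partner = NA_character_, has_acd = FALSE) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  n <- length(seqs)
  new("DomainRecordSet", seqs = seqs,
      parent = rep_len(parent, n), start = as.integer(rep_len(start, n)),
      end = as.integer(rep_len(end, n)),
      provenance = rep_len(provenance, n),
      partner = rep_len(as.character(partner), n),
      hasAcd = rep_len(has_acd, n))
}

#' Concatenate two DomainRecordSets
#' @param x,y DomainRecordSets
#' @export
combineDomainRecords <- function(x, y) {
  new("DomainRecordSet",
      seqs = c(x@seqs, y@seqs), parent = c(x@parent, y@parent),
      start = c(x@start, y@start), end = c(x@end, y@end),
      provenance = c(x@provenance, y@provenance),
      partner = c(x@partner, y@partner),
      hasAcd = c(x@hasAcd, y@hasAcd))
}

#' Split a pseudodimer parent into two monomer-equivalent halves
#'
#' The split point is s = floor((first_end + second_start) / 2); the
#' N-half covers parent residues 1..s, the C-half s+1..L, so the two
#' halves tile the parent exactly.
#'
#' @param parent_seq parent residues (character or AAString)
#' @param parent_id parent protein id
#' @param first,second integer length-2 intervals (start, end) of the
#'   two domain hits on the parent; `first` must end before `second`
#'   starts
#' @return a [DomainRecordSet-class] with two mutually linked records
#'   (ids `<parent_id>_N` and `<parent_id>_C`)
#' @export
splitPseudodimer <- function(parent_seq, parent_id, first, second) {
  parent_seq <- as.character(parent_seq)
  L <- nchar(parent_seq)
  stopifnot(length(first) == 2L, length(second) == 2L)
  if (first[1] > first[2] || second[1] > second[2])
    stop("malformed interval")
  if (first[2] >= second[1])
    stop("overlapping intervals: first domain must end before the ",
         "second starts")
  if (second[2] > L) stop("interval exceeds parent length")
  s <- floor((first[2] + second[1]) / 2)
  ids <- paste0(parent_id, c("_N", "_C"))
  halves <- c(substr(parent_seq, 1L, s), substr(parent_seq, s + 1L, L))
  names(halves) <- ids
  domainRecordSet(halves, parent = parent_id,
                  start = c(1L, s + 1L), end = c(s, L),
                  provenance = c("pseudodimer_N", "pseudodimer_C"),
                  partner = rev(ids), has_acd = FALSE)
}

#' Cut complete hits on one parent into domain records
#'
#' One complete hit yields a single-domain record covering the hit
#' interval.  Two (or more) non-overlapping hits mark a pseudodimer:
#' the parent is cut at successive midpoints between consecutive hits,
#' left to right, and consecutive parts are pair-linked.
#'
#' @param parent_seq parent residues
#' @param parent_id parent id
#' @param hits data.frame of this parent's complete hits (columns
#'   start, end), non-overlapping
#' @return a [DomainRecordSet-class]
#' @export
cutDomains <- function(parent_seq, parent_id, hits) {
  parent_seq <- as.character(parent_seq)
  L <- nchar(parent_seq)
  hits <- hits[order(hits$start), , drop = FALSE]
  k <- nrow(hits)
  if (k == 0L) stop("no hits to cut")
  if (k == 1L) {
    res <- substr(parent_seq, hits$start, hits$end)
    names(res) <- parent_id
    return(domainRecordSet(res, parent_id, hits$start, hits$end))
  }
  if (any(hits$start[-1] <= hits$end[-k]))
    stop("overlapping intervals")
  cuts <- floor((hits$end[-k] + hits$start[-1]) / 2)
  lo <- c(1L, cuts + 1L)
  hi <- c(cuts, L)
  ids <- if (k == 2L) paste0(parent_id, c("_N", "_C"))
         else paste0(parent_id, "_part", seq_len(k))
  res <- substring(parent_seq, lo, hi)
  names(res) <- ids
  prov <- c("pseudodimer_N",
            rep(c("pseudodimer_C", "pseudodimer_N"),
                length.out = k - 1L))
  # consecutive pairing (1,2), (3,4), ...; odd tail left unpaired
  partner <- rep(NA_character_, k)
  for (i in seq(1L, k - 1L, by = 2L)) {
    partner[i] <- ids[i + 1L]
    partner[i + 1L] <- ids[i]
  }
  domainRecordSet(res, parent_id, lo, hi, provenance = prov,
                  partner = partner)
}
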