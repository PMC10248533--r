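# FASTA input/output on top of Biostrings.

# Accept either a file path or raw FASTA text ('>' anywhere at line start).
as_fasta_file <- function(path_or_text) {
  if (length(path_or_text) == 1L && !grepl("[\n>]", path_or_text) &&
      file.exists(path_or_text))
    return(path_or_text)
  tf <- tempfile(fileext = ".fasta")
  writeLines(path_or_text, tf)
  tf
}

#' Read protein sequences from FASTA
#'
#' Reads a FASTA file (or raw FASTA text) into an `AAStringSet`.  Record
#' ids are the first whitespace-delimited token of each header; the
#' remainder is kept as a `description` metadata column.  Residues are
#' upper-cased and trailing '*' terminators stripped.
#'
#' @param path_or_text file path, or a character scalar/vector of FASTA
#'   text
#' @param allow_gaps if FALSE (default), gap characters in the input are
#'   an error; use [readAlignedFasta()] for alignments
#' @return AAStringSet named by record id
#' @export
readFastaRecords <- function(path_or_text, allow_gaps = FALSE) {
  f <- as_fasta_file(paste(path_or_text, collapse = "\n"))
  ss <- Biostrings::readAAStringSet(f)
  if (length(ss) == 0L) stop("no records in FASTA input")
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate id in FASTA input: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chars <- toupper(as.character(ss))
  chars <- sub("\\*$", "", chars)
  chars <- gsub(".", "-", chars, fixed = TRUE)
  if (!allow_gaps && any(grepl("-", chars, fixed = TRUE)))
    stop("gap characters found; use readAlignedFasta() for alignments")
  if (any(nchar(chars) == 0L)) stop("empty sequence in FASTA input")
  out <- Biostrings::AAStringSet(chars)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs AAStringSet (or named character vector)
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFastaRecords <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Construct an AlignmentBlock
#'
#' @param rows named character vector of equal-width gapped rows, or an
#'   AAStringSet
#' @return AlignmentBlock
#' @export
alignmentBlock <- function(rows) {
  if (methods::is(rows, "XStringSet")) {
    nm <- names(rows)
    rows <- as.character(rows)
    names(rows) <- nm
  }
  rows <- toupper(rows)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  new("AlignmentBlock", rows = rows,
      width = if (length(rows)) nchar(rows[[1]]) else 0L)
}

#' Read an aligned FASTA file into an AlignmentBlock
#'
#' '.' gaps are normalised to '-'.
#'
#' @inheritParams readFastaRecords
#' @return AlignmentBlock
#' @export
readAlignedFasta <- function(path_or_text) {
  f <- as_fasta_file(paste(path_or_text, collapse = "\n"))
  ss <- Biostrings::readAAStringSet(f)
  if (length(ss) == 0L) stop("no records in FASTA input")
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate id in FASTA input")
  rows <- as.character(ss)
  names(rows) <- ids
  alignmentBlock(rows)
}

#' Write an AlignmentBlock as aligned FASTA
#'
#' @param block AlignmentBlock
#' @param path output file
#' @export
writeAlignedFasta <- function(block, path) {
  writeFastaRecords(alignmentRows(block), path)
}

#' Remove gaps from gapped rows
#'
#' @param x character vector of gapped sequences
#' @return character vector without '-'
#' @export
ungapRows <- function(x) gsub("-", "", x, fixed = TRUE)
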