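# Minimal fixed-column PDB coordinate reader/writer.
#
# Only ATOM/HETATM/TER/MODEL/ENDMDL records are interpreted; the first
# model is kept, waters are dropped by default, and alternate locations
# are resolved to the highest-occupancy conformer (ties broken by the
# alphabetically first altloc id).  The element is taken from columns
# 77-78 when present, otherwise inferred from the atom name.

pdb_substr <- function(lines, a, b) {
  out <- substr(lines, a, b)
  trimws(out)
}

infer_element <- function(atom_name) {
  # strip leading digits (e.g. "1HB"), take first letter; two-letter
  # elements in proteins are rare and covered by the explicit field
  first <- sub("^[0-9]*", "", atom_name)
  toupper(substr(first, 1, 1))
}

#' Read a PDB-format coordinate subset
#'
#' @param path_or_text path to a PDB file, or PDB text
#' @param keep_waters keep HOH/WAT HETATM records (default FALSE)
#' @return a [StructureModel-class]
#' @export
readPdbModel <- function(path_or_text, keep_waters = FALSE) {
  txt <- paste(path_or_text, collapse = "\n")
  if (!grepl("\n", txt) && file.exists(txt))
    lines <- readLines(txt)
  else
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  # first model only
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  rec <- trimws(rec[keep])
  resid <- pdb_substr(lines, 18, 20)
  if (!keep_waters) {
    w <- resid %in% c("HOH", "WAT", "DOD")
    lines <- lines[!w]; rec <- rec[!w]; resid <- resid[!w]
  }
  if (length(lines) == 0L) stop("empty structure: no ATOM records")
  element <- pdb_substr(lines, 77, 78)
  atom <- pdb_substr(lines, 13, 16)
  element <- ifelse(element == "", infer_element(atom), element)
  atoms <- data.frame(
    record = rec,
    atom = atom,
    altloc = substr(lines, 17, 17),
    resid = resid,
    chain = substr(lines, 22, 22),
    resno = as.integer(pdb_substr(lines, 23, 26)),
    insert = trimws(substr(lines, 27, 27)),
    x = as.numeric(pdb_substr(lines, 31, 38)),
    y = as.numeric(pdb_substr(lines, 39, 46)),
    z = as.numeric(pdb_substr(lines, 47, 54)),
    occ = suppressWarnings(as.numeric(pdb_substr(lines, 55, 60))),
    element = element,
    stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1.0
  atoms$altloc[atoms$altloc == " "] <- ""
  # altloc resolution: per (chain, resno, insert, atom) keep the
  # highest-occupancy conformer, ties to the alphabetically first id
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom,
               sep = "\r")
  atoms$idx0 <- seq_len(nrow(atoms))
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(key[ord]), ]
  atoms <- atoms[order(atoms$idx0), ]        # restore file order
  atoms$record <- NULL
  atoms$altloc <- NULL
  atoms$idx0 <- NULL
  rownames(atoms) <- NULL
  new("StructureModel",
      atoms = atoms[c("chain", "resno", "insert", "resid", "atom",
                      "element", "x", "y", "z", "occ")])
}

#' Write a StructureModel as PDB text
#'
#' @param s StructureModel
#' @param path optional output file
#' @return character vector of PDB lines (invisibly when written)
#' @export
writePdbModel <- function(s, path = NULL) {
  a <- atomTable(s)
  name4 <- ifelse(nchar(a$atom) >= 4, substr(a$atom, 1, 4),
                  sprintf(" %-3s", a$atom))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name4, a$resid, a$chain, a$resno,
    ifelse(a$insert == "", " ", a$insert), a$x, a$y, a$z, a$occ, 0,
    a$element)
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# split an atom table into residues (list of data.frames, chain order)
residue_split <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  split(atoms, factor(key, levels = unique(key)))
}

#' One-letter sequence of a chain
#'
#' @param s StructureModel
#' @param chain chain identifier
#' @return character scalar ('X' for nonstandard residues)
#' @export
chainSequence <- function(s, chain) {
  a <- atomTable(s)
  a <- a[a$chain == chain, ]
  if (nrow(a) == 0L) stop("no such chain: ", chain)
  res <- a[!duplicated(paste(a$resno, a$insert)), ]
  letters1 <- RES3TO1[res$resid]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' Subset a StructureModel by chain
#'
#' @param s StructureModel
#' @param chains chain identifiers to keep
#' @return StructureModel
#' @export
subsetChains <- function(s, chains) {
  a <- atomTable(s)
  a <- a[a$chain %in% chains, ]
  if (nrow(a) == 0L) stop("empty structure: no atoms in selection")
  rownames(a) <- NULL
  new("StructureModel", atoms = a)
}
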