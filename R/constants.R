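# Shared residue-level constants.

# canonical amino-acid order used for all profile and model matrices
AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Kyte-Doolittle hydropathy scale
#'
#' Published per-residue hydropathy values (Kyte & Doolittle 1982,
#' J Mol Biol 157:105-132), indexed by three-letter residue name.
#' Positive values are hydrophobic.
#'
#' @format Named numeric vector of length 20.
#' @export
kyteDoolittleScale <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5
)

# three-letter -> one-letter residue names
RES3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# van der Waals radii (Angstrom) for SASA; fixed for reproducibility
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# side-chain atoms forming salt bridges
SB_BASIC <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                 HIS = c("ND1", "NE2"))
SB_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA20, AA20]
    }
    cache
  }
})
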