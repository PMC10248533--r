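# Central S4 containers.
#
# Trees are deliberately NOT wrapped: the package uses ape's `phylo`
# objects throughout (branch lengths on `edge.length`, bootstrap supports
# as numeric strings on `node.label`), which keeps the whole ape/phytools
# toolbox directly applicable.

#' @import methods
NULL

#' Gapped multiple sequence alignment
#'
#' An ordered set of aligned rows over the 20 canonical amino acids plus
#' 'X', with '-' as the only gap character ('.' is normalised to '-' on
#' construction).  All rows have identical width and ungapping any row
#' yields a valid, nonempty sequence.
#'
#' @slot rows named character vector of gapped rows (names are unique ids)
#' @slot width integer column count
#' @export
setClass("AlignmentBlock",
  representation(rows = "character", width = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@rows) == 0L) msg <- c(msg, "alignment has no rows")
    if (is.null(names(object@rows)) || anyDuplicated(names(object@rows)))
      msg <- c(msg, "row ids must be present and unique")
    if (length(object@rows) &&
        !all(nchar(object@rows) == object@width))
      msg <- c(msg, "all rows must have length equal to width")
    ung <- gsub("-", "", object@rows, fixed = TRUE)
    if (any(nchar(ung) == 0L))
      msg <- c(msg, "ungapped rows must be nonempty")
    if (length(msg)) msg else TRUE
  })

#' Position-specific scoring model for a domain family
#'
#' Log-odds scores (bits) per match column over the 20 amino acids,
#' derived from a seed alignment; columns with more than 50% gaps are
#' excluded from the match-state set.
#'
#' @slot scores 20 x width numeric matrix of log-odds bit scores,
#'   rows in ARNDCQEGHILKMFPSTWYV order
#' @slot background named background frequencies (sum to 1)
#' @slot matchColumns integer indices of the seed columns retained
#' @slot consensus character vector, highest-scoring residue per column
#' @slot gapOpen,gapExtend positive gap penalties (bits)
#' @export
setClass("ProfileModel",
  representation(scores = "matrix", background = "numeric",
                 matchColumns = "integer", consensus = "character",
                 gapOpen = "numeric", gapExtend = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@scores) != 20L)
      msg <- c(msg, "scores must have 20 rows")
    if (abs(sum(object@background) - 1) > 1e-8)
      msg <- c(msg, "background frequencies must sum to 1")
    if (object@gapOpen <= 0 || object@gapExtend <= 0)
      msg <- c(msg, "gap penalties must be positive")
    if (length(msg)) msg else TRUE
  })

#' Harvested monomer domains with pseudodimer provenance
#'
#' Each record is a monomer-equivalent Get3/ArsA-like domain cut from a
#' parent protein.  Pseudodimer halves carry symmetric partner links and
#' concatenating a pair's residues reproduces the parent sequence of the
#' split region exactly.
#'
#' @slot seqs AAStringSet of domain residues, names are record ids
#' @slot parent character, parent protein id per record
#' @slot start,end integer, 1-based inclusive interval on the parent
#' @slot provenance character, one of "single", "pseudodimer_N",
#'   "pseudodimer_C"
#' @slot partner character, id of the other pseudodimer half or NA
#' @slot hasAcd logical, alpha-crystallin-domain flag
#' @export
setClass("DomainRecordSet",
  representation(seqs = "AAStringSet", parent = "character",
                 start = "integer", end = "integer",
                 provenance = "character", partner = "character",
                 hasAcd = "logical"),
  validity = function(object) {
    n <- length(object@seqs)
    msg <- character()
    if (anyDuplicated(names(object@seqs)))
      msg <- c(msg, "record ids must be unique")
    for (sl in c("parent", "start", "end", "provenance", "partner",
                 "hasAcd"))
      if (length(slot(object, sl)) != n)
        msg <- c(msg, sprintf("slot '%s' must have length %d", sl, n))
    bad <- !object@provenance %in%
      c("single", "pseudodimer_N", "pseudodimer_C")
    if (any(bad)) msg <- c(msg, "unknown provenance tag")
    # partner links must be symmetric
    has <- !is.na(object@partner)
    if (any(has)) {
      ids <- names(object@seqs)
      p <- object@partner[has]
      if (!all(p %in% ids)) {
        msg <- c(msg, "partner ids must be present in the set")
      } else {
        back <- object@partner[match(p, ids)]
        if (!identical(back, ids[has]))
          msg <- c(msg, "partner links must be symmetric")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Greedy identity clustering result
#'
#' @slot clusters named list: representative id -> character vector of all
#'   member ids (the representative included)
#' @slot threshold identity fraction used
#' @slot group free-text group tag (e.g. "plants")
#' @export
setClass("ClusterSet",
  representation(clusters = "list", threshold = "numeric",
                 group = "character"),
  validity = function(object) {
    msg <- character()
    if (object@threshold <= 0 || object@threshold > 1)
      msg <- c(msg, "threshold must be in (0, 1]")
    mem <- unlist(object@clusters, use.names = FALSE)
    if (anyDuplicated(mem))
      msg <- c(msg, "a sequence may belong to only one cluster")
    if (length(msg)) msg else TRUE
  })

#' Reversible amino-acid substitution model
#'
#' A general time-reversible rate matrix Q built from published
#' exchangeabilities and equilibrium frequencies, normalised so the
#' expected rate at equilibrium is one substitution per site
#' (sum_i pi_i Q_ii = -1).
#'
#' @slot name model name ("LG", "VT" or "TOY3")
#' @slot states character state alphabet
#' @slot exchangeabilities symmetric matrix of relative rates
#' @slot freqs equilibrium frequencies
#' @slot Q normalised rate matrix
#' @slot eig eigen machinery for fast P(t) = exp(Qt) (list: values,
#'   vectors, inverse)
#' @export
setClass("SubstitutionModel",
  representation(name = "character", states = "character",
                 exchangeabilities = "matrix", freqs = "numeric",
                 Q = "matrix", eig = "list"),
  validity = function(object) {
    msg <- character()
    k <- length(object@states)
    if (!all(dim(object@Q) == k)) msg <- c(msg, "Q dimension mismatch")
    if (max(abs(rowSums(object@Q))) > 1e-8)
      msg <- c(msg, "Q rows must sum to 0")
    db <- object@freqs * object@Q - t(object@freqs * object@Q)
    if (max(abs(db)) > 1e-8)
      msg <- c(msg, "detailed balance violated")
    if (abs(sum(object@freqs) - 1) > 1e-8)
      msg <- c(msg, "frequencies must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' Likelihood-based placement of one query on a reference tree
#'
#' @slot query query id
#' @slot bestEdge edge index (row of the reference tree's edge matrix)
#'   attaining the maximum placement likelihood
#' @slot pendantLength optimized pendant branch length at the best edge
#' @slot logLik log-likelihood of the best placement
#' @slot edgeTable data.frame with one row per reference edge: edge,
#'   pendant, logLik
#' @export
setClass("PlacementResult",
  representation(query = "character", bestEdge = "integer",
                 pendantLength = "numeric", logLik = "numeric",
                 edgeTable = "data.frame"),
  validity = function(object) {
    et <- object@edgeTable
    if (nrow(et) &&
        abs(max(et$logLik) - object@logLik) > 1e-9)
      "bestEdge must attain the maximum of the per-edge table"
    else TRUE
  })

#' Subfamily assignment and taxonomic distribution summary
#'
#' @slot labels named character: leaf id -> subfamily label or
#'   "unassigned"
#' @slot presence logical genus x subfamily matrix ("a homolog was
#'   identified in at least one member of the genus")
#' @slot copyCounts integer organism x subfamily matrix
#' @export
setClass("CladeAtlas",
  representation(labels = "character", presence = "matrix",
                 copyCounts = "matrix"))

#' Atomic coordinates (PDB ATOM/HETATM subset, first model)
#'
#' A flat atom table in the spirit of bio3d: one row per atom after
#' altloc resolution, with chain, residue and coordinate columns.
#'
#' @slot atoms data.frame with columns chain, resno, insert, resid,
#'   atom, element, x, y, z, occ
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame"),
  validity = function(object) {
    a <- object@atoms
    need <- c("chain", "resno", "insert", "resid", "atom", "element",
              "x", "y", "z", "occ")
    if (!all(need %in% names(a)))
      return("missing atom-table columns")
    if (nrow(a) && !all(is.finite(c(a$x, a$y, a$z))))
      return("coordinates must be finite")
    TRUE
  })

#' Rigid-body superposition result
#'
#' @slot rotation 3x3 orthonormal matrix, det = +1
#' @slot translation length-3 vector (Angstrom)
#' @slot rmsd root-mean-square deviation after superposition (Angstrom)
#' @slot n number of paired atoms used
#' @export
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", n = "integer"),
  validity = function(object) {
    R <- object@rotation
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      return("rotation must be orthonormal")
    if (det(R) < 0) return("rotation must not be a reflection")
    TRUE
  })

#' Buried-interface report for a two-part partition of a structure
#'
#' @slot partA,partB chain identifiers of the two sides
#' @slot deltaSasaTotal SASA(A) + SASA(B) - SASA(A+B), in Angstrom^2
#' @slot deltaSasaHalf half of the total (the common interface-area
#'   convention)
#' @slot contacts data.frame of cross-interface residue contacts with a
#'   type column in {salt bridge, hydrogen bond candidate, hydrophobic}
#' @export
setClass("InterfaceReport",
  representation(partA = "character", partB = "character",
                 deltaSasaTotal = "numeric", deltaSasaHalf = "numeric",
                 contacts = "data.frame"),
  validity = function(object) {
    if (object@deltaSasaTotal < -1e-6)
      return("buried area cannot be negative")
    if (abs(object@deltaSasaHalf - object@deltaSasaTotal / 2) > 1e-9)
      return("half convention must equal total/2")
    TRUE
  })

#' A complete synthetic gene-family study
#'
#' Everything one run of the generator emits: the species tree, the gene
#' trees, the emitted protein records (pseudodimer parents already fused,
#' accessory domains already appended), per-record truth, the pseudodimer
#' pair map and the proteome metadata table.  Byte-identical given the
#' same seed.
#'
#' @slot speciesTree ape phylo, ultrametric, with clade tags in
#'   `cladeTags`
#' @slot cladeTags named character: species -> clade tag
#' @slot geneTrees named list of ape phylo, one per subfamily
#' @slot proteins AAStringSet of emitted (parent-level) protein sequences
#' @slot truth data.frame: one row per emitted domain copy (id, parent,
#'   species, subfamily, provenance, has_acd)
#' @slot pairMap named character: pseudodimer half id -> partner id
#' @slot taxonomy data.frame in readTaxonomyTable() layout
#' @slot domainSeed AlignmentBlock: stand-in for the structure-based
#'   seed alignment of the domain family
#' @slot acdSeed AlignmentBlock: seed alignment for the accessory
#'   alpha-crystallin domain
#' @slot anchors named list: subfamily -> anchor leaf ids
#' @slot seed integer RNG seed used
#' @export
setClass("FamilySimulation",
  representation(speciesTree = "ANY", cladeTags = "character",
                 geneTrees = "list", proteins = "AAStringSet",
                 truth = "data.frame", pairMap = "character",
                 taxonomy = "data.frame", domainSeed = "AlignmentBlock",
                 acdSeed = "AlignmentBlock", anchors = "list",
                 seed = "integer"))
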