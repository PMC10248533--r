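# Generics, show methods and accessors.

#' @importClassesFrom Biostrings AAStringSet
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#'   pairwiseAlignment alignedPattern alignedSubject
#' @importFrom S4Vectors mcols "mcols<-" DataFrame
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize runif rpois rbinom rexp setNames sd
#' @importFrom utils data read.delim
#' @useDynLib Get3Atlas, .registration = TRUE
NULL

#' Alignment width (column count)
#' @param x an AlignmentBlock
#' @return integer
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' @rdname alignmentWidth
#' @export
setMethod("alignmentWidth", "AlignmentBlock", function(x) x@width)

#' Alignment rows as gapped character strings
#' @param x an AlignmentBlock
#' @return named character vector
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))

#' @rdname alignmentRows
#' @export
setMethod("alignmentRows", "AlignmentBlock", function(x) x@rows)

#' Character matrix view of an alignment (rows x columns)
#' @param x an AlignmentBlock
#' @export
setMethod("as.matrix", "AlignmentBlock", function(x) {
  m <- do.call(rbind, strsplit(x@rows, ""))
  rownames(m) <- names(x@rows)
  m
})

#' Match-state columns of a profile
#' @param x a ProfileModel
#' @return integer vector of seed column indices
#' @export
setGeneric("matchColumns", function(x) standardGeneric("matchColumns"))

#' @rdname matchColumns
#' @export
setMethod("matchColumns", "ProfileModel", function(x) x@matchColumns)

#' Profile width (number of match columns)
#' @param x a ProfileModel
#' @export
setGeneric("profileWidth", function(x) standardGeneric("profileWidth"))

#' @rdname profileWidth
#' @export
setMethod("profileWidth", "ProfileModel", function(x) ncol(x@scores))

#' Profile consensus sequence
#' @param x a ProfileModel
#' @export
setGeneric("profileConsensus",
           function(x) standardGeneric("profileConsensus"))

#' @rdname profileConsensus
#' @export
setMethod("profileConsensus", "ProfileModel",
          function(x) paste(x@consensus, collapse = ""))

#' Cluster representatives
#' @param x a ClusterSet
#' @export
setGeneric("clusterRepresentatives",
           function(x) standardGeneric("clusterRepresentatives"))

#' @rdname clusterRepresentatives
#' @export
setMethod("clusterRepresentatives", "ClusterSet",
          function(x) names(x@clusters))

#' Cluster membership (representative -> member ids)
#' @param x a ClusterSet
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname clusterMembers
#' @export
setMethod("clusterMembers", "ClusterSet", function(x) x@clusters)

#' Domain sequences of a DomainRecordSet
#' @param x a DomainRecordSet
#' @export
setGeneric("domainSequences",
           function(x) standardGeneric("domainSequences"))

#' @rdname domainSequences
#' @export
setMethod("domainSequences", "DomainRecordSet", function(x) x@seqs)

#' Domain metadata as a data.frame
#' @param x a DomainRecordSet
#' @export
setGeneric("domainTable", function(x) standardGeneric("domainTable"))

#' @rdname domainTable
#' @export
setMethod("domainTable", "DomainRecordSet", function(x) {
  data.frame(id = names(x@seqs), parent = x@parent, start = x@start,
             end = x@end, provenance = x@provenance, partner = x@partner,
             has_acd = x@hasAcd, row.names = NULL,
             stringsAsFactors = FALSE)
})

#' Atom table of a StructureModel
#' @param x a StructureModel
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' Per-edge placement table
#' @param x a PlacementResult
#' @export
setGeneric("placementTable",
           function(x) standardGeneric("placementTable"))

#' @rdname placementTable
#' @export
setMethod("placementTable", "PlacementResult", function(x) x@edgeTable)

#' Leaf -> subfamily labels of a CladeAtlas
#' @param x a CladeAtlas
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))

#' @rdname leafLabels
#' @export
setMethod("leafLabels", "CladeAtlas", function(x) x@labels)

#' Genus x subfamily presence matrix
#' @param x a CladeAtlas
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname presenceMatrix
#' @export
setMethod("presenceMatrix", "CladeAtlas", function(x) x@presence)

#' Organism x subfamily copy-number matrix
#' @param x a CladeAtlas
#' @export
setGeneric("copyCounts", function(x) standardGeneric("copyCounts"))

#' @rdname copyCounts
#' @export
setMethod("copyCounts", "CladeAtlas", function(x) x@copyCounts)

setMethod("show", "AlignmentBlock", function(object) {
  cat(sprintf("AlignmentBlock: %d rows x %d columns\n",
              length(object@rows), object@width))
})

setMethod("show", "ProfileModel", function(object) {
  cat(sprintf("ProfileModel: %d match columns, gap open/extend %.2f/%.2f bits\n",
              ncol(object@scores), object@gapOpen, object@gapExtend))
})

setMethod("show", "DomainRecordSet", function(object) {
  tab <- table(object@provenance)
  cat(sprintf("DomainRecordSet: %d domains (%s); %d with alphaCD\n",
              length(object@seqs),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              sum(object@hasAcd)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet('%s'): %d clusters over %d sequences at %.0f%% identity\n",
              object@group, length(object@clusters),
              length(unlist(object@clusters)), 100 * object@threshold))
})

setMethod("show", "SubstitutionModel", function(object) {
  cat(sprintf("SubstitutionModel %s: %d states, expected rate 1 sub/site\n",
              object@name, length(object@states)))
})

setMethod("show", "PlacementResult", function(object) {
  cat(sprintf("PlacementResult '%s': best edge %d (pendant %.4g, lnL %.4f)\n",
              object@query, object@bestEdge, object@pendantLength,
              object@logLik))
})

setMethod("show", "CladeAtlas", function(object) {
  cat(sprintf("CladeAtlas: %d leaves labelled, %d genera x %d subfamilies\n",
              sum(object@labels != "unassigned"), nrow(object@presence),
              ncol(object@presence)))
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel: %d atoms, %d residues, chains %s\n",
              nrow(a), nrow(unique(a[c("chain", "resno", "insert")])),
              paste(unique(a$chain), collapse = ",")))
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition over %d atom pairs: RMSD %.3f A\n",
              object@n, object@rmsd))
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf(
    "InterfaceReport %s|%s: buried %.0f A^2 total (%.0f A^2 half), %d contacts\n",
    paste(object@partA, collapse = "+"),
    paste(object@partB, collapse = "+"),
    object@deltaSasaTotal, object@deltaSasaHalf, nrow(object@contacts)))
})

setMethod("show", "FamilySimulation", function(object) {
  cat(sprintf(
    "FamilySimulation (seed %d): %d species, %d subfamilies, %d domain copies\n",
    object@seed, length(object@speciesTree$tip.label),
    length(object@geneTrees), nrow(object@truth)))
})
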