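# Clade assignment by anchor proteins and the taxonomic summaries built
# from it: subfamily labels, monophyly tests, genus-level
# presence/absence, photosynthesis classification and copy-number
# tallies.

#' Assign leaves to subfamilies by anchor proteins
#'
#' Each anchor set (e.g. the A. thaliana Get3a/b/c/d proteins plus the
#' rooting anchors) defines a subfamily clade: the largest clade of the
#' rooted tree containing every anchor of that set and no anchor of any
#' other set.  All leaves inside the clade receive its label; leaves in
#' no anchor clade are "unassigned".
#'
#' @param phy rooted ape `phylo` (typically the support-collapsed tree,
#'   so weakly supported attachments fall to "unassigned")
#' @param anchors named list: subfamily label -> character vector of
#'   anchor tip labels
#' @return named character vector: tip label -> subfamily label or
#'   "unassigned"
#' @export
assignClades <- function(phy, anchors) {
  if (is.null(names(anchors)) || anyDuplicated(names(anchors)))
    stop("anchor sets must have unique labels")
  all_anchor <- unlist(anchors, use.names = FALSE)
  missing_anchor <- setdiff(all_anchor, phy$tip.label)
  if (length(missing_anchor))
    stop("anchor absent from tree: ",
         paste(missing_anchor, collapse = ", "))
  n_tip <- length(phy$tip.label)
  sets <- node_leafsets(phy)
  parent <- integer(n_tip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  labels <- setNames(rep("unassigned", n_tip), phy$tip.label)
  for (lab in names(anchors)) {
    own <- anchors[[lab]]
    foreign <- setdiff(all_anchor, own)
    node <- if (length(own) == 1L) match(own, phy$tip.label)
            else ape::getMRCA(phy, own)
    if (any(foreign %in% sets[[node]]))
      stop("anchors not separable: set '", lab,
           "' has no clade free of foreign anchors")
    # climb while the parent clade still excludes all foreign anchors
    while (parent[node] != 0L &&
           !any(foreign %in% sets[[parent[node]]]) &&
           parent[node] != node) {
      node <- parent[node]
    }
    labels[sets[[node]]] <- lab
  }
  labels
}

#' Is a leaf set monophyletic on a rooted tree?
#'
#' @param phy rooted ape `phylo`
#' @param leaves character vector of tip labels
#' @return TRUE iff some clade's leaf set equals `leaves` exactly
#' @export
testMonophyly <- function(phy, leaves) {
  unknown <- setdiff(leaves, phy$tip.label)
  if (length(unknown))
    stop("unknown leaf: ", paste(unknown, collapse = ", "))
  target <- paste(sort(unique(leaves)), collapse = "\r")
  sets <- node_leafsets(phy)
  any(vapply(sets, function(s) paste(s, collapse = "\r") == target,
             logical(1)))
}

#' Genus-level presence/absence of subfamilies
#'
#' A cell (genus, subfamily) is TRUE iff at least one leaf labelled
#' with that subfamily maps to an organism of that genus.  Leaves
#' without taxonomy are counted as missing (with a warning) and
#' "unassigned" leaves are excluded.
#'
#' @param labels named character vector from [assignClades()]
#' @param taxonomy data.frame from [readTaxonomyTable()]
#' @param leaf_organism named character: leaf id -> organism
#' @return logical matrix, rows = genera present in `taxonomy`,
#'   columns = subfamily labels
#' @export
genusPresenceMatrix <- function(labels, taxonomy, leaf_organism) {
  subfam <- sort(unique(labels[labels != "unassigned"]))
  genera <- unique(taxonomy$genus)
  M <- matrix(FALSE, nrow = length(genera), ncol = length(subfam),
              dimnames = list(genera, subfam))
  lab <- labels[labels != "unassigned"]
  for (leaf in names(lab)) {
    org <- leaf_organism[leaf]
    if (is.na(org)) {
      warning("leaf without organism mapping: ", leaf)
      next
    }
    g <- taxonomy$genus[match(org, taxonomy$organism)]
    if (is.na(g)) {
      warning("leaf without taxonomy: ", leaf)
      next
    }
    M[g, lab[leaf]] <- TRUE
  }
  M
}

#' Classify an organism as putatively photosynthetic
#'
#' TRUE iff the proteome contains strictly more than 10 proteins
#' annotated with the photosynthesis GO term (GO:0015979).
#'
#' @param taxon one row of a taxonomy data.frame, or a count vector
#' @return logical
#' @export
classifyPhotosynthetic <- function(taxon) {
  count <- if (is.data.frame(taxon)) taxon$go_photosynthesis_count
           else as.numeric(taxon)
  count > 10
}

#' Filter proteomes by annotation quality
#'
#' Keeps organisms flagged as reference or nonredundant, or with BUSCO
#' completeness strictly above 75%.
#'
#' @param taxa taxonomy data.frame from [readTaxonomyTable()]
#' @return filtered data.frame
#' @export
proteomeQualityFilter <- function(taxa) {
  if (nrow(taxa) == 0L) return(taxa)
  keep <- vapply(seq_len(nrow(taxa)), function(i) {
    flags <- taxa$proteome_flags[[i]]
    any(c("reference", "nonredundant") %in% flags) ||
      (!is.na(taxa$busco_completeness[i]) &&
         taxa$busco_completeness[i] > 75)
  }, logical(1))
  taxa[keep, , drop = FALSE]
}

#' Per-organism subfamily copy numbers
#'
#' @param labels named character vector from [assignClades()]
#' @param leaf_organism named character: leaf id -> organism
#' @return integer matrix, organisms (sorted) x subfamilies
#' @export
copyNumberTally <- function(labels, leaf_organism) {
  lab <- labels[labels != "unassigned"]
  if (length(lab) == 0L)
    return(matrix(0L, 0, 0))
  org <- leaf_organism[names(lab)]
  tab <- table(factor(org), factor(lab))
  M <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  M[order(rownames(M)), , drop = FALSE]
}

#' Build a CladeAtlas from an assigned tree and metadata
#'
#' @param labels named character vector from [assignClades()]
#' @param taxonomy taxonomy data.frame
#' @param leaf_organism named character: leaf id -> organism
#' @return a [CladeAtlas-class]
#' @export
buildCladeAtlas <- function(labels, taxonomy, leaf_organism) {
  new("CladeAtlas", labels = labels,
      presence = genusPresenceMatrix(labels, taxonomy, leaf_organism),
      copyCounts = copyNumberTally(labels, leaf_organism))
}
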