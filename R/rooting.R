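# Post-hoc rooting at the edge ancestral to the most recent common
# ancestor of two designated anchor taxa (the study design roots
# between the bacterial ArsA and archaeal Get3 anchors).

#' Root a tree at the MRCA of two anchor taxa
#'
#' On the unrooted tree, the root is placed on the edge immediately
#' ancestral to the most recent common ancestor of the two anchors,
#' splitting that edge at its midpoint.  If the MRCA coincides with the
#' virtual root, the edge separating the side containing `taxonA` is
#' used instead.
#'
#' @param phy ape `phylo` (rooted input is unrooted first, making the
#'   operation idempotent)
#' @param taxonA,taxonB anchor tip labels
#' @return rooted ape `phylo`
#' @export
rootAtMrca <- function(phy, taxonA, taxonB) {
  missing_taxa <- setdiff(c(taxonA, taxonB), phy$tip.label)
  if (length(missing_taxa))
    stop("taxon absent from tree: ",
         paste(missing_taxa, collapse = ", "))
  u <- ape::unroot(phy)
  if (is.null(u$edge.length))
    u$edge.length <- rep(1, nrow(u$edge))
  n_tip <- length(u$tip.label)
  # orient the unrooted tree from the tip farthest from both anchors,
  # so "the MRCA of A and B" is well defined and does not depend on
  # the arbitrary internal storage order
  others <- setdiff(u$tip.label, c(taxonA, taxonB))
  if (length(others)) {
    dt <- ape::cophenetic.phylo(u)
    far <- others[which.max(pmin(dt[others, taxonA],
                                 dt[others, taxonB]))]
    u <- ape::root(u, outgroup = far, resolve.root = FALSE,
                   edgelabel = TRUE)
  }
  m <- ape::getMRCA(u, c(taxonA, taxonB))
  if (m == n_tip + 1L) {
    # MRCA fell on the virtual root: use the root child whose clade
    # separates taxonA's side from taxonB's side
    sets <- node_leafsets(u)
    kids <- u$edge[u$edge[, 1] == m, 2]
    m <- kids[vapply(kids, function(k)
      taxonA %in% sets[[k]] && !(taxonB %in% sets[[k]]),
      logical(1))][1]
  }
  er <- which(u$edge[, 2] == m)
  pos <- u$edge.length[er] / 2
  phytools::reroot(u, m, position = pos)
}
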