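# Nonparametric bootstrap supports and support-based collapse.

# resample alignment columns with replacement
resample_columns <- function(msa, idx) {
  m <- as.matrix(msa)[, idx, drop = FALSE]
  alignmentBlock(apply(m, 1, paste, collapse = ""))
}

#' Bootstrap supports for a maximum-likelihood tree
#'
#' Columns are resampled with replacement; each replicate tree is
#' inferred by neighbor-joining on ML distances, one branch-length
#' sweep and one NNI round.  The support of an internal edge of the
#' reference tree is the percentage of replicate trees containing its
#' bipartition.
#'
#' @param msa an [AlignmentBlock-class]
#' @param model a [SubstitutionModel-class]
#' @param replicates number of bootstrap replicates (>= 1).  The study
#'   tooling this emulates used fixed totals of 400 (family-wide tree)
#'   or 100 (representative tree)
#' @param seed RNG seed
#' @param tree optional reference tree; inferred with [mlTree()] when
#'   NULL
#' @return the reference tree with supports (0-100) on `node.label`
#'   (root label empty) and attribute "boot_trees"
#' @export
bootstrapSupports <- function(msa, model, replicates, seed = 1,
                              tree = NULL) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.null(tree)) tree <- mlTree(msa, model)
  width <- alignmentWidth(msa)
  boot <- with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      idx <- sample.int(width, width, replace = TRUE)
      rep_msa <- resample_columns(msa, idx)
      D <- mlPairwiseDistances(rep_msa, model)
      phy <- njStartTree(D)
      phy <- optimizeBranchLengths(phy, rep_msa, model, max_sweeps = 1)
      nniSearch(phy, rep_msa, model, max_rounds = 1, resweep = FALSE)
    })
  })
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  sup <- round(100 * counts / replicates)
  lab <- as.character(sup)
  lab[1] <- ""                      # root has no support
  tree$node.label <- lab
  attr(tree, "boot_trees") <- boot
  tree
}

#' Collapse weakly supported branchpoints
#'
#' Contracts every internal edge whose support is strictly below the
#' threshold, producing a multifurcating tree; edges with support at or
#' above the threshold, and edges without a numeric support, are kept.
#'
#' @param phy tree with supports on `node.label`
#' @param threshold support percentage (default 70: nodes with less
#'   than 70\% bootstrap support are collapsed)
#' @return multifurcating ape `phylo`
#' @export
collapseLowSupport <- function(phy, threshold = 70) {
  sup <- nodeSupports(phy)
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  drop_nodes <- which(!is.na(sup) & sup < threshold) + n_tip
  drop_nodes <- setdiff(drop_nodes, root)
  if (length(drop_nodes) == 0L) return(phy)
  tmp <- phy
  if (is.null(tmp$edge.length))
    tmp$edge.length <- rep(1, nrow(tmp$edge))
  is_drop_edge <- tmp$edge[, 2] %in% drop_nodes
  saved <- tmp$edge.length
  tmp$edge.length[is_drop_edge] <- 0
  tmp$edge.length[!is_drop_edge] <- pmax(saved[!is_drop_edge], 1e-6)
  out <- ape::di2multi(tmp, tol = 1e-9)
  # restore true lengths on surviving edges (matched by child clade)
  if (!is.null(phy$edge.length)) {
    orig_clades <- node_leafsets(phy)
    new_clades <- node_leafsets(out)
    key_orig <- vapply(orig_clades, paste, character(1), collapse = "\r")
    key_new <- vapply(new_clades, paste, character(1), collapse = "\r")
    m <- match(key_new[out$edge[, 2]], key_orig[phy$edge[, 2]])
    ok <- !is.na(m)
    out$edge.length[ok] <- phy$edge.length[m[ok]]
  } else {
    out$edge.length <- NULL
  }
  out
}

# leaf-label set below every node (sorted), as a list indexed by node
node_leafsets <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- phy$tip.label[i]
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1]; ch <- po$edge[r, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}
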