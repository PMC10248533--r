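# Seedable generators for synthetic gene-family studies: a species tree
# with clade structure (photosynthetic bacteria, single-celled plants,
# land plants), gene families evolving by duplication/loss with
# domain-fusion (pseudodimer) and accessory-domain gain, sequences
# evolved under an empirical substitution model, proteome GO-count
# tables, and toy dimer coordinates with computable interface burial.

#' Simulate (or echo) an ultrametric species tree
#'
#' @param n_taxa number of tips (>= 3); ignored when `topology` is
#'   given
#' @param seed RNG seed
#' @param topology optional fixed ape `phylo`, echoed unchanged
#' @param depth root-to-tip depth in substitutions/site (simulated
#'   trees are rescaled to this)
#' @param birth,death birth-death rates for the simulated topology
#' @param clade_tags optional named list tag -> tip labels, attached as
#'   attribute "cladeTags" (named character tip -> tag)
#' @return ultrametric ape `phylo`
#' @export
simulateSpeciesTree <- function(n_taxa = 8, seed = 1, topology = NULL,
                                depth = 0.5, birth = 1, death = 0,
                                clade_tags = NULL) {
  if (is.null(topology)) {
    if (n_taxa < 3) stop("need at least 3 taxa")
    phy <- with_seed(seed, ape::rphylo(n_taxa, birth, death))
    phy$tip.label <- paste0("sp", seq_len(n_taxa))
    h <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * depth / h
  } else {
    phy <- topology
  }
  if (!is.null(clade_tags)) {
    tags <- rep(NA_character_, length(phy$tip.label))
    names(tags) <- phy$tip.label
    for (tg in names(clade_tags)) tags[clade_tags[[tg]]] <- tg
    attr(phy, "cladeTags") <- tags
  }
  phy
}

# --- birth-death gene evolution inside a species tree ----------------

new_counter <- function() {
  e <- new.env()
  e$n <- 0L
  e
}

next_gene_id <- function(counter, species) {
  counter$n <- counter$n + 1L
  sprintf("%s_g%d", species, counter$n)
}

# evolve one gene lineage from a point on the species tree; returns
# NULL (lineage lost) or list(core = newick without top length,
# len = pending branch length, tips = data.frame(tip, species))
bd_lineage <- function(phy, node, remaining, dup, loss, counter) {
  rate <- dup + loss
  te <- if (rate > 0) rexp(1, rate) else Inf
  if (te < remaining) {
    if (runif(1) < dup / max(rate, 1e-300)) {
      l <- bd_lineage(phy, node, remaining - te, dup, loss, counter)
      r <- bd_lineage(phy, node, remaining - te, dup, loss, counter)
      return(join_lineages(list(l, r), te))
    }
    return(NULL)                                   # loss
  }
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) {
    sp <- phy$tip.label[node]
    tip <- next_gene_id(counter, sp)
    return(list(core = tip, len = remaining,
                tips = data.frame(tip = tip, species = sp,
                                  stringsAsFactors = FALSE)))
  }
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  lens <- phy$edge.length[match(kids, phy$edge[, 2])]
  parts <- lapply(seq_along(kids), function(i)
    bd_lineage(phy, kids[i], lens[i], dup, loss, counter))
  join_lineages(parts, remaining)
}

join_lineages <- function(parts, pending) {
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) return(NULL)
  if (length(parts) == 1L) {
    p <- parts[[1]]
    p$len <- p$len + pending
    return(p)
  }
  inner <- paste(vapply(parts, function(p)
    sprintf("%s:%.8f", p$core, p$len), character(1)), collapse = ",")
  list(core = sprintf("(%s)", inner), len = pending,
       tips = do.call(rbind, lapply(parts, `[[`, "tips")))
}

#' Simulate one gene family inside a species tree
#'
#' Birth-death gene evolution (duplication rate, loss rate per
#' lineage per unit branch length), with optional forced loss in a
#' configured clade (emulating the loss of the chloroplast subfamily in
#' single-celled plants), accessory-domain gain restricted to a clade,
#' and sampling-based domain fusion.
#'
#' @param species_tree ape `phylo` with branch lengths
#' @param duplication_rate,loss_rate non-negative rates
#' @param fusion_prob probability that a species' first two gene copies
#'   are emitted as one fused pseudodimer parent (requires >= 2 copies)
#' @param acd_gain_clade species names whose gene copies carry the
#'   accessory alpha-crystallin domain
#' @param forced_loss_clade species names in which the family is
#'   deterministically absent
#' @param seed RNG seed
#' @param counter optional shared gene-id counter (internal use)
#' @return list: `tree` (ape phylo gene tree, NULL when < 2 surviving
#'   copies), `truth` (data.frame: tip, species, has_acd, fused_with)
#' @export
simulateGeneFamily <- function(species_tree, duplication_rate = 0,
                               loss_rate = 0, fusion_prob = 0,
                               acd_gain_clade = character(),
                               forced_loss_clade = character(),
                               seed = 1, counter = NULL) {
  if (duplication_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (is.null(counter)) counter <- new_counter()
  res <- with_seed(seed, {
    root <- length(species_tree$tip.label) + 1L
    lin <- bd_lineage(species_tree, root, 0, duplication_rate,
                      loss_rate, counter)
    fuse_draw <- runif(length(species_tree$tip.label))
    list(lin = lin, fuse_draw = fuse_draw)
  })
  lin <- res$lin
  if (is.null(lin))
    return(list(tree = NULL,
                truth = data.frame(tip = character(),
                                   species = character(),
                                   has_acd = logical(),
                                   fused_with = character(),
                                   stringsAsFactors = FALSE)))
  truth <- lin$tips
  drop <- truth$tip[truth$species %in% forced_loss_clade]
  tree <- NULL
  if (nrow(truth) - length(drop) >= 2L) {
    tree <- ape::read.tree(text = sprintf("%s:%.8f;", lin$core,
                                          lin$len))
    if (length(drop))
      tree <- ape::drop.tip(tree, drop)
  }
  truth <- truth[!truth$tip %in% drop, , drop = FALSE]
  truth$has_acd <- truth$species %in% acd_gain_clade
  # fusion: per species with >= 2 copies, fuse the first two
  truth$fused_with <- NA_character_
  names(res$fuse_draw) <- species_tree$tip.label
  for (sp in unique(truth$species)) {
    rows <- which(truth$species == sp)
    if (length(rows) >= 2L && fusion_prob > 0 &&
        res$fuse_draw[sp] < fusion_prob) {
      truth$fused_with[rows[1]] <- truth$tip[rows[2]]
      truth$fused_with[rows[2]] <- truth$tip[rows[1]]
    }
  }
  list(tree = tree, truth = truth)
}

#' Evolve sequences down a gene tree
#'
#' The root sequence is drawn from the model's equilibrium frequencies
#' (or supplied); each branch substitutes site-independently with
#' P(t) = exp(Qt).  Indel-free by default so the true alignment is the
#' sequence matrix itself; a simple geometric indel mode is available.
#'
#' @param gene_tree ape `phylo` with branch lengths in
#'   substitutions/site
#' @param root_length number of sites (ignored when `root_seq` given)
#' @param model a [SubstitutionModel-class]
#' @param seed RNG seed
#' @param root_seq optional integer state vector for the root
#' @param indel_rate per-site probability of a deletion event per
#'   branch (default 0 = indel-free)
#' @return AAStringSet of tip sequences ('-' never appears; deletions
#'   remove residues)
#' @export
evolveSequences <- function(gene_tree, root_length = 500, model,
                            seed = 1, root_seq = NULL,
                            indel_rate = 0) {
  k <- length(model@states)
  with_seed(seed, {
    if (is.null(root_seq))
      root_seq <- sample.int(k, root_length, replace = TRUE,
                             prob = model@freqs)
    n_tip <- length(gene_tree$tip.label)
    n_node <- n_tip + gene_tree$Nnode
    seqs <- vector("list", n_node)
    root <- n_tip + 1L
    seqs[[root]] <- root_seq
    po <- ape::reorder.phylo(gene_tree, "postorder")
    edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
    elens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
    for (r in seq_len(nrow(edges))) {
      u <- edges[r, 1]; v <- edges[r, 2]
      P <- transitionProbability(model, elens[r])
      parent <- seqs[[u]]
      child <- integer(length(parent))
      for (st in seq_len(k)) {
        at <- which(parent == st)
        if (length(at))
          child[at] <- sample.int(k, length(at), replace = TRUE,
                                  prob = P[st, ])
      }
      if (indel_rate > 0) {
        del <- runif(length(child)) < indel_rate
        if (any(del) && !all(del)) child <- child[!del]
      }
      seqs[[v]] <- child
    }
    out <- vapply(seq_len(n_tip), function(i)
      paste(model@states[seqs[[i]]], collapse = ""), character(1))
    names(out) <- gene_tree$tip.label
    Biostrings::AAStringSet(out)
  })
}

#' Generate a proteome metadata table
#'
#' Photosynthetic-clade species receive GO:0015979 counts of at least
#' 11 (11 + Poisson(30)); the rest at most 10 (uniform on 0..10).
#' BUSCO completeness is uniform on [60, 100] with 20% missing;
#' reference/nonredundant flags are independent coin flips (p = 0.5 /
#' 0.3).
#'
#' @param species character vector of organism names
#'   ("Genus_species")
#' @param photosynthetic_species subset of `species`
#' @param seed RNG seed
#' @param superkingdom named character (default "Eukaryota" for all)
#' @return data.frame in [readTaxonomyTable()] layout
#'   (`proteome_flags` as a list column)
#' @export
makeProteomeTables <- function(species, photosynthetic_species,
                               seed = 1, superkingdom = NULL) {
  if (is.null(superkingdom))
    superkingdom <- setNames(rep("Eukaryota", length(species)),
                             species)
  with_seed(seed, {
    photo <- species %in% photosynthetic_species
    go <- integer(length(species))
    go[photo] <- 11L + rpois(sum(photo), 30)
    go[!photo] <- sample(0:10, sum(!photo), replace = TRUE)
    busco <- round(runif(length(species), 60, 100), 1)
    busco[runif(length(species)) < 0.2] <- NA_real_
    flags <- lapply(seq_along(species), function(i) {
      f <- character()
      if (runif(1) < 0.5) f <- c(f, "reference")
      if (runif(1) < 0.3) f <- c(f, "nonredundant")
      f
    })
    out <- data.frame(
      organism = species,
      genus = vapply(strsplit(species, "_"), `[[`, character(1), 1),
      superkingdom = unname(superkingdom[species]),
      go_photosynthesis_count = go,
      busco_completeness = busco,
      stringsAsFactors = FALSE)
    out$proteome_flags <- flags
    out
  })
}

# --- toy coordinates -------------------------------------------------

ideal_helix_atoms <- function(n_res, chain, origin = c(0, 0, 0),
                              flip = FALSE, resno_start = 1L) {
  # ideal alpha-helix: CA radius 2.3 A, rise 1.5 A, twist 100 deg
  rows <- list()
  for (i in seq_len(n_res)) {
    ang <- (i - 1) * 100 * pi / 180
    z <- (i - 1) * 1.5
    if (flip) z <- -z
    ca <- c(2.3 * cos(ang), 2.3 * sin(ang), z) + origin
    offs <- list(N = c(-0.8, 0.9, -0.9), C = c(0.7, -0.6, 1.0),
                 O = c(1.4, -1.2, 1.2), CB = c(1.2, 1.1, -0.3))
    rot <- matrix(c(cos(ang), -sin(ang), 0,
                    sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
    atoms <- rbind(
      data.frame(atom = "CA", element = "C", x = ca[1], y = ca[2],
                 z = ca[3]),
      do.call(rbind, lapply(names(offs), function(a) {
        p <- ca + as.numeric(rot %*% offs[[a]])
        data.frame(atom = a, element = substr(a, 1, 1), x = p[1],
                   y = p[2], z = p[3])
      })))
    atoms$chain <- chain
    atoms$resno <- resno_start + i - 1L
    atoms$insert <- ""
    atoms$resid <- "ALA"
    atoms$occ <- 1
    rows[[i]] <- atoms
  }
  do.call(rbind, rows)
}

#' Build a toy two-helix dimer with computable interface burial
#'
#' Two ideal poly-Ala alpha-helices (CA radius 2.3 A, rise 1.5 A,
#' twist 100 deg) with axes separated by `separation` along x; chain A
#' runs +z, chain B -z.  Optionally appends an Arg (chain A) / Asp
#' (chain B) side-chain pair at a configured nitrogen-oxygen distance
#' for salt-bridge tests.
#'
#' @param separation axial separation in Angstrom (> 0)
#' @param seed RNG seed (0.01 A coordinate jitter breaks exact
#'   symmetry)
#' @param n_res residues per helix (default 20)
#' @param salt_bridge_distance if non-NULL, N-O distance (Angstrom) of
#'   the appended Arg/Asp pair
#' @return a [StructureModel-class]
#' @export
makeToyDimer <- function(separation = 8, seed = 1, n_res = 20,
                         salt_bridge_distance = NULL) {
  if (separation <= 0) stop("separation must be positive")
  a <- ideal_helix_atoms(n_res, "A", origin = c(0, 0, 0))
  b <- ideal_helix_atoms(n_res, "B",
                         origin = c(separation, 0, (n_res - 1) * 1.5),
                         flip = TRUE)
  atoms <- rbind(a, b)
  if (!is.null(salt_bridge_distance)) {
    mid_z <- (n_res - 1) * 1.5 / 2
    nh1 <- c(separation / 2 - salt_bridge_distance / 2, 6, mid_z)
    od1 <- c(separation / 2 + salt_bridge_distance / 2, 6, mid_z)
    extra <- data.frame(
      atom = c("NH1", "CZ", "OD1", "CG"),
      element = c("N", "C", "O", "C"),
      x = c(nh1[1], nh1[1] - 1.3, od1[1], od1[1] + 1.3),
      y = c(nh1[2], nh1[2], od1[2], od1[2]),
      z = c(nh1[3], nh1[3] + 0.5, od1[3], od1[3] + 0.5),
      chain = c("A", "A", "B", "B"),
      resno = n_res + 1L, insert = "",
      resid = c("ARG", "ARG", "ASP", "ASP"), occ = 1,
      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, extra)
  }
  atoms <- with_seed(seed, {
    atoms$x <- atoms$x + runif(nrow(atoms), -0.01, 0.01)
    atoms$y <- atoms$y + runif(nrow(atoms), -0.01, 0.01)
    atoms$z <- atoms$z + runif(nrow(atoms), -0.01, 0.01)
    atoms
  })
  atoms <- atoms[order(atoms$chain, atoms$resno), ]
  rownames(atoms) <- NULL
  new("StructureModel",
      atoms = atoms[c("chain", "resno", "insert", "resid", "atom",
                      "element", "x", "y", "z", "occ")])
}
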