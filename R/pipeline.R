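# The end-to-end synthetic study: generate a gene family with known
# truth, then run harvest -> cluster -> align -> tree -> bootstrap ->
# collapse -> placement -> rooting -> clade assignment and compare the
# result against the truth tables.

# derived sub-seed, kept inside 32-bit integer range
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k * 7919) %% 2147483647L) + 1L
}

#' Default configuration of the synthetic family study
#'
#' Eight species in three clades (two photosynthetic bacteria, two
#' single-celled plants, four land plants; root-to-tip depth 0.5
#' substitutions/site) carry four subfamilies: Get3a and Get3b/c in all
#' plants, Get3d (with an appended alpha-crystallin domain) in
#' photosynthetic bacteria and land plants but deterministically lost
#' in single-celled plants, and ArsA-like tandem pseudodimers in the
#' photosynthetic bacteria only.  Domains are 500 sites, evolved
#' indel-free under LG.
#'
#' @return named list of generator settings
#' @export
defaultFamilyConfig <- function() {
  species_newick <- paste0(
    "((Nostoc_punctiforme:0.25,Synechocystis_sp:0.25):0.25,",
    "((Chlamydomonas_reinhardtii:0.2,Ostreococcus_tauri:0.2):0.15,",
    "((Arabidopsis_thaliana:0.12,Oryza_sativa:0.12):0.08,",
    "(Physcomitrium_patens:0.15,Marchantia_polymorpha:0.15):0.05)",
    ":0.15):0.15);")
  clade_tags <- list(
    cyanobacteria = c("Nostoc_punctiforme", "Synechocystis_sp"),
    single_celled_plants = c("Chlamydomonas_reinhardtii",
                             "Ostreococcus_tauri"),
    land_plants = c("Arabidopsis_thaliana", "Oryza_sativa",
                    "Physcomitrium_patens", "Marchantia_polymorpha"))
  cyano <- clade_tags$cyanobacteria
  plants <- c(clade_tags$single_celled_plants, clade_tags$land_plants)
  list(
    species_newick = species_newick,
    clade_tags = clade_tags,
    anchor_species = "Arabidopsis_thaliana",
    n_sites = 500L,
    acd_sites = 110L,
    linker_sites = 20L,
    model = "LG",
    duplication_rate = 0.08,
    loss_rate = 0,
    # the subfamily ancestors radiate hierarchically, mirroring the
    # family's deep structure: (Get3a, Get3b/c) against (Get3d, ArsA)
    family_split = list(left = c("Get3a", "Get3bc"),
                        right = c("Get3d", "ArsA")),
    split_branch = 0.15,
    # root branch = divergence of the subfamily ancestor from the
    # family root; half_branch = extra divergence between the N and C
    # halves of the fused pseudodimer subfamily
    half_branch = 0.3,
    subfamilies = list(
      Get3a = list(root_branch = 0.50, absent = cyano,
                   has_acd = FALSE, fused = FALSE),
      Get3bc = list(root_branch = 0.50, absent = cyano,
                    has_acd = FALSE, fused = FALSE),
      Get3d = list(root_branch = 0.50,
                   absent = clade_tags$single_celled_plants,
                   has_acd = TRUE, fused = FALSE),
      ArsA = list(root_branch = 0.60, absent = plants,
                  has_acd = FALSE, fused = TRUE)))
}

mutate_states <- function(states_vec, model, t) {
  k <- length(model@states)
  P <- transitionProbability(model, t)
  out <- integer(length(states_vec))
  for (st in seq_len(k)) {
    at <- which(states_vec == st)
    if (length(at))
      out[at] <- sample.int(k, length(at), replace = TRUE,
                            prob = P[st, ])
  }
  out
}

states_to_string <- function(states_vec, model) {
  paste(model@states[states_vec], collapse = "")
}

#' Generate a complete synthetic family study
#'
#' Draws the family root domain, evolves subfamily ancestors along
#' their root branches, runs birth-death gene evolution inside the
#' species tree per subfamily (with the configured deterministic
#' absences), evolves domain sequences down each gene tree, appends
#' the accessory alpha-crystallin domain where configured, fuses the
#' pseudodimer subfamily's two half-domains around a linker, and emits
#' the proteome metadata plus seed alignments for harvesting.
#'
#' @param seed integer RNG seed; the whole object is a pure function
#'   of (config, seed)
#' @param config list from [defaultFamilyConfig()]
#' @return a [FamilySimulation-class]
#' @export
familySimulation <- function(seed = 1, config = defaultFamilyConfig()) {
  model <- substitutionModel(config$model, "model")
  sp_tree <- readNewickTree(config$species_newick)
  tags <- setNames(rep(NA_character_, length(sp_tree$tip.label)),
                   sp_tree$tip.label)
  for (tg in names(config$clade_tags))
    tags[config$clade_tags[[tg]]] <- tg

  root_seq <- with_seed(sub_seed(seed, 0), {
    sample.int(length(model@states), config$n_sites, replace = TRUE,
               prob = model@freqs)
  })
  acd_root <- with_seed(sub_seed(seed, 1), {
    sample.int(length(model@states), config$acd_sites, replace = TRUE,
               prob = model@freqs)
  })

  counter <- new_counter()
  gene_trees <- list()
  truth_rows <- list()
  proteins <- character()
  pair_map <- character()
  seed_rows <- character()

  # internal nodes of the family tree: two sides of the basal split
  split_br <- config$split_branch %||% 0
  side_seq <- list(
    left = with_seed(sub_seed(seed, 2),
                     mutate_states(root_seq, model, split_br)),
    right = with_seed(sub_seed(seed, 3),
                      mutate_states(root_seq, model, split_br)))

  for (si in seq_along(config$subfamilies)) {
    sub_name <- names(config$subfamilies)[si]
    sub <- config$subfamilies[[si]]
    side <- if (!is.null(config$family_split) &&
                sub_name %in% config$family_split$right) "right"
            else "left"
    sub_root <- with_seed(sub_seed(seed, 10 + si), {
      mutate_states(side_seq[[side]], model,
                    max(sub$root_branch - split_br, 0.05))
    })
    seed_rows[[sub_name]] <- states_to_string(sub_root, model)
    fam <- simulateGeneFamily(
      sp_tree, duplication_rate = config$duplication_rate,
      loss_rate = config$loss_rate,
      forced_loss_clade = sub$absent,
      acd_gain_clade = if (sub$has_acd)
        setdiff(sp_tree$tip.label, sub$absent) else character(),
      seed = sub_seed(seed, 20 + si), counter = counter)
    if (is.null(fam$tree) || nrow(fam$truth) == 0L) next
    gene_trees[[sub_name]] <- fam$tree

    if (!sub$fused) {
      seqs <- evolveSequences(fam$tree, model = model,
                              seed = sub_seed(seed, 30 + si),
                              root_seq = sub_root)
      seq_chr <- setNames(as.character(seqs), names(seqs))
      if (sub$has_acd) {
        acd_seqs <- evolveSequences(fam$tree, model = model,
                                    seed = sub_seed(seed, 40 + si),
                                    root_seq = acd_root)
        acd_chr <- setNames(as.character(acd_seqs), names(acd_seqs))
      }
      for (tip in fam$truth$tip) {
        prot <- seq_chr[[tip]]
        if (sub$has_acd) prot <- paste0(prot, acd_chr[[tip]])
        proteins[[tip]] <- prot
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          id = tip, parent = tip,
          species = fam$truth$species[fam$truth$tip == tip],
          subfamily = sub_name, provenance = "single",
          has_acd = sub$has_acd, stringsAsFactors = FALSE)
      }
    } else {
      # ancient tandem fusion: N and C halves evolve from two
      # paralogous roots down the same gene tree
      rootN <- with_seed(sub_seed(seed, 50 + si),
                         mutate_states(sub_root, model,
                                       config$half_branch))
      rootC <- with_seed(sub_seed(seed, 60 + si),
                         mutate_states(sub_root, model,
                                       config$half_branch))
      seqN <- evolveSequences(fam$tree, model = model,
                              seed = sub_seed(seed, 70 + si),
                              root_seq = rootN)
      seqC <- evolveSequences(fam$tree, model = model,
                              seed = sub_seed(seed, 80 + si),
                              root_seq = rootC)
      linker <- with_seed(sub_seed(seed, 90 + si), {
        sample.int(length(model@states), config$linker_sites,
                   replace = TRUE, prob = model@freqs)
      })
      linker_chr <- states_to_string(linker, model)
      chrN <- setNames(as.character(seqN), names(seqN))
      chrC <- setNames(as.character(seqC), names(seqC))
      for (tip in fam$truth$tip) {
        proteins[[tip]] <- paste0(chrN[[tip]], linker_chr, chrC[[tip]])
        sp <- fam$truth$species[fam$truth$tip == tip]
        idN <- paste0(tip, "_N"); idC <- paste0(tip, "_C")
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          id = c(idN, idC), parent = tip, species = sp,
          subfamily = sub_name,
          provenance = c("pseudodimer_N", "pseudodimer_C"),
          has_acd = FALSE, stringsAsFactors = FALSE)
        pair_map[[idN]] <- idC
        pair_map[[idC]] <- idN
      }
    }
  }
  truth <- do.call(rbind, truth_rows)

  # seed alignments (stand-ins for the structure-based seeds):
  # subfamily ancestor domains, plus evolved variants for the alphaCD
  acd_var1 <- with_seed(sub_seed(seed, 101),
                        mutate_states(acd_root, model, 0.3))
  acd_var2 <- with_seed(sub_seed(seed, 102),
                        mutate_states(acd_root, model, 0.3))
  acd_seed_rows <- c(acd_anc = states_to_string(acd_root, model),
                     acd_v1 = states_to_string(acd_var1, model),
                     acd_v2 = states_to_string(acd_var2, model))

  photo <- unname(unlist(config$clade_tags))
  superk <- setNames(ifelse(sp_tree$tip.label %in%
                              config$clade_tags$cyanobacteria,
                            "Bacteria", "Eukaryota"),
                     sp_tree$tip.label)
  taxonomy <- makeProteomeTables(sp_tree$tip.label,
                                 photosynthetic_species = photo,
                                 seed = sub_seed(seed, 103),
                                 superkingdom = superk)

  anchors <- list()
  for (sub_name in names(config$subfamilies)) {
    rows <- truth[truth$subfamily == sub_name, , drop = FALSE]
    anc <- rows[rows$species == config$anchor_species, , drop = FALSE]
    if (nrow(anc) == 0L)           # subfamily absent from the anchor
      anc <- rows                  # species: fall back to any member
    anchors[[sub_name]] <- anc$id[anc$parent == anc$parent[1]]
  }

  new("FamilySimulation", speciesTree = sp_tree, cladeTags = tags,
      geneTrees = gene_trees,
      proteins = Biostrings::AAStringSet(proteins), truth = truth,
      pairMap = pair_map, taxonomy = taxonomy,
      domainSeed = alignmentBlock(seed_rows),
      acdSeed = alignmentBlock(acd_seed_rows), anchors = anchors,
      seed = as.integer(seed))
}

# cluster-group tag of one domain record, mirroring the tiered
# clustering of the source analysis
record_group <- function(species, has_acd, tags) {
  tag <- tags[species]
  if (!is.na(tag) && tag == "cyanobacteria") {
    if (has_acd) "photo_bact_acd" else "photo_bact"
  } else if (!is.na(tag)) "plants" else "other"
}

default_tiers <- c(plants = 0.85, photo_bact_acd = 0.70,
                   photo_bact = 0.65, other = 0.60)

# label an EPA-placed query from the leaf labels flanking its edge
placement_label <- function(tree, edge_row, labels) {
  sets <- node_leafsets(tree)
  below <- sets[[tree$edge[edge_row, 2]]]
  above <- setdiff(tree$tip.label, below)
  lab_of <- function(leaves) {
    u <- unique(labels[leaves])
    u <- u[!is.na(u)]
    if (length(u) == 1L && u != "unassigned") u else NA_character_
  }
  lb <- lab_of(below)
  if (!is.na(lb)) return(lb)
  la <- lab_of(above)
  if (!is.na(la)) return(la)
  "unassigned"
}

#' Run the full comparative pipeline on a synthetic family
#'
#' Harvest (iterative profile search, completeness filter, pseudodimer
#' splitting, alphaCD flagging), tiered greedy clustering with
#' paired-half retention, seed-anchored alignment of representatives,
#' ML tree with bootstrap supports and 70% collapse, keep-length
#' addition and likelihood placement of non-representatives, MRCA
#' rooting, anchor-based clade assignment and the genus presence /
#' copy-number summaries, plus recovery statistics against the
#' generator truth.
#'
#' @param sim a [FamilySimulation-class]
#' @param tiers named identity thresholds per cluster group
#' @param bootstrap_replicates bootstrap replicate count (default 20;
#'   the emulated study used 400/100 at full scale)
#' @param collapse_threshold support collapse threshold (default 70)
#' @param iterations profile-search iterations (default 3)
#' @param coverage completeness fraction (default 0.9)
#' @param model_name substitution model for tree inference (default
#'   "VT" with its published frequencies, as in the emulated
#'   representative-tree stage)
#' @param verbose log each stage (with the RNG seed of every
#'   stochastic stage) via message()
#' @return list with all intermediate products and `recovery`
#'   statistics (label_recovery, harvested_fraction,
#'   forced_absences_ok, atlas, labels)
#' @export
runFamilyPipeline <- function(sim, tiers = default_tiers,
                              bootstrap_replicates = 20,
                              collapse_threshold = 70,
                              iterations = 3, coverage = 0.9,
                              model_name = "VT", verbose = FALSE) {
  seed <- sim@seed
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  # 1. harvest
  say("harvest: iterative profile search, seed ", sub_seed(seed, 201))
  profile <- buildProfile(sim@domainSeed)
  hits <- iterativeSearch(profile, sim@proteins,
                          iterations = iterations,
                          seed = sub_seed(seed, 201))
  hits <- completenessFilter(hits, fraction = coverage)
  acd_profile <- buildProfile(sim@acdSeed)
  acd_thr <- calibrateBitThreshold(acd_profile, sim@proteins,
                                   seed = sub_seed(seed, 202))
  prot_chr <- setNames(as.character(sim@proteins),
                       names(sim@proteins))
  records <- NULL
  for (pid in unique(hits$parent_id)) {
    ph <- hits[hits$parent_id == pid, , drop = FALSE]
    # keep non-overlapping hits, best first
    ph <- ph[order(-ph$score), , drop = FALSE]
    kept <- ph[1, , drop = FALSE]
    for (r in seq_len(nrow(ph))[-1]) {
      if (all(ph$start[r] > kept$end | ph$end[r] < kept$start))
        kept <- rbind(kept, ph[r, , drop = FALSE])
    }
    rec <- cutDomains(prot_chr[[pid]], pid, kept)
    has <- detectAcd(prot_chr[[pid]], acd_profile, acd_thr)$has_acd
    rec@hasAcd <- rep(has, length(rec@seqs))
    records <- if (is.null(records)) rec
               else combineDomainRecords(records, rec)
  }
  rec_tab <- domainTable(records)
  rec_seqs <- setNames(as.character(records@seqs),
                       names(records@seqs))
  leaf_species <- setNames(
    sim@truth$species[match(rec_tab$parent, sim@truth$parent)],
    rec_tab$id)

  # 2. tiered clustering + paired-half retention
  say("cluster: tiered greedy clustering")
  groups <- vapply(seq_len(nrow(rec_tab)), function(i)
    record_group(leaf_species[rec_tab$id[i]], rec_tab$has_acd[i],
                 sim@cladeTags), character(1))
  reps <- character()
  cluster_sets <- list()
  for (g in unique(groups)) {
    thr <- if (g %in% names(tiers)) tiers[[g]] else 0.6
    cs <- greedyCluster(rec_seqs[rec_tab$id[groups == g]], thr,
                        group = g)
    cluster_sets[[g]] <- cs
    reps <- c(reps, clusterRepresentatives(cs))
  }
  dom_pairs <- setNames(rec_tab$partner, rec_tab$id)
  reps <- keepPairHalves(reps, dom_pairs)
  # anchors are always included alongside the representatives
  anchor_ids <- intersect(unlist(sim@anchors), rec_tab$id)
  reps <- union(reps, anchor_ids)

  # 3. seed-anchored alignment of representatives
  say("align: ", length(reps), " representatives onto the seed")
  aln <- alignToSeed(rec_seqs[reps], sim@domainSeed)
  # the seed rows anchored the columns but are not study sequences
  aln_reps <- alignmentBlock(
    alignmentRows(aln)[setdiff(names(alignmentRows(aln)),
                               names(alignmentRows(sim@domainSeed)))])

  # 4. ML tree, bootstrap, collapse
  model <- if (model_name == "LG")
    substitutionModel("LG", "empirical", alignment = aln_reps)
  else substitutionModel(model_name, "model")
  say("tree: ML inference under ", model_name)
  tree <- mlTree(aln_reps, model)
  say("bootstrap: ", bootstrap_replicates, " replicates, seed ",
      sub_seed(seed, 203))
  tree <- bootstrapSupports(aln_reps, model,
                            replicates = bootstrap_replicates,
                            seed = sub_seed(seed, 203), tree = tree)
  collapsed <- collapseLowSupport(tree, collapse_threshold)

  # 5. rooting + clade assignment on the collapsed tree
  anchors <- lapply(sim@anchors, intersect, collapsed$tip.label)
  anchors <- anchors[lengths(anchors) > 0]
  # root between the ArsA-like outgroup and everything else: with the
  # two pseudodimer halves as anchors the root lands on the edge
  # above their clade, which is the family's deepest split
  if (!is.null(anchors$ArsA) && length(anchors$ArsA) >= 2) {
    root_a <- anchors$ArsA[1]
    root_b <- anchors$ArsA[2]
  } else {
    root_a <- anchors[[length(anchors)]][1]
    root_b <- anchors[[1]][1]
  }
  say("root: MRCA of ", root_a, " and ", root_b)
  rooted <- rootAtMrca(collapsed, root_a, root_b)
  labels <- assignClades(rooted, anchors)

  # 6. keep-length addition + likelihood placement of
  #    non-representatives
  nonreps <- setdiff(rec_tab$id, reps)
  say("place: ", length(nonreps), " non-representatives")
  placements <- list()
  for (q in nonreps) {
    row <- addKeepLength(aln_reps, rec_seqs[[q]])
    pl <- epaPlace(row$row, tree, aln_reps, model, query_id = q)
    placements[[q]] <- pl
    labels[q] <- placement_label(tree, pl@bestEdge, labels)
  }

  # 7. taxonomic summaries
  atlas <- buildCladeAtlas(labels, sim@taxonomy, leaf_species)

  # 8. recovery against truth
  truth_lab <- setNames(sim@truth$subfamily, sim@truth$id)
  harvested <- intersect(names(truth_lab), names(labels))
  correct <- sum(labels[harvested] == truth_lab[harvested])
  label_recovery <- correct / length(truth_lab)
  harvested_fraction <- length(harvested) / length(truth_lab)
  # forced absences: subfamily x absent-clade cells must stay empty
  cfg_absent <- list(Get3d = c("Chlamydomonas", "Ostreococcus"))
  pres <- presenceMatrix(atlas)
  absences_ok <- TRUE
  for (sf in names(cfg_absent)) {
    gg <- intersect(cfg_absent[[sf]], rownames(pres))
    if (sf %in% colnames(pres) && length(gg))
      absences_ok <- absences_ok && !any(pres[gg, sf])
  }
  list(hits = hits, records = records, clusters = cluster_sets,
       reps = reps, alignment = aln_reps, tree = tree,
       collapsed = collapsed, rooted = rooted, labels = labels,
       placements = placements, atlas = atlas,
       recovery = list(label_recovery = label_recovery,
                       harvested_fraction = harvested_fraction,
                       forced_absences_ok = absences_ok))
}
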