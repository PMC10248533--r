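# Substitution models, pruning likelihood, NJ, branch-length
# optimization, NNI, bootstrap, collapse, placement and rooting.

toy <- substitutionModel("TOY3")

test_that("substitution models satisfy rate-matrix invariants", {
  for (m in list(toy, substitutionModel("LG"),
                 substitutionModel("VT"))) {
    expect_lt(max(abs(rowSums(m@Q))), 1e-10)
    expect_lt(max(abs(m@freqs * m@Q - t(m@freqs * m@Q))), 1e-10)
    expect_equal(-sum(m@freqs * diag(m@Q)), 1, tolerance = 1e-10)
    for (t in c(0.01, 0.1, 1, 10)) {
      P <- transitionProbability(m, t)
      expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    }
  }
  # empirical frequencies are counted from the alignment
  ab <- alignmentBlock(c(a = "AAAAAAAARN", b = "AAAAAAAARN"))
  emp <- substitutionModel("LG", "empirical", alignment = ab)
  expect_equal(emp@freqs[["A"]], (16 + 1) / (20 + 20))
})

test_that("eigendecomposition P(t) matches scaling-and-squaring expm", {
  skip_if_not_installed("Matrix")
  for (m in list(toy, substitutionModel("LG"))) {
    for (t in c(0.01, 0.1, 1, 10)) {
      Pe <- transitionProbability(m, t)
      Ps <- as.matrix(Matrix::expm(Matrix::Matrix(m@Q * t)))
      expect_lt(max(abs(Pe - unname(Ps))), 1e-8)
    }
  }
})

test_that("pruning equals exhaustive enumeration on small TOY3 trees", {
  # 3-taxon star
  msa3 <- alignmentBlock(c(A = "ABCA", B = "ABCB", C = "AACC"))
  tr3 <- readNewickTree("(A:0.3,B:0.4,C:0.5);")
  Pa <- transitionProbability(toy, 0.3)
  Pb <- transitionProbability(toy, 0.4)
  Pc <- transitionProbability(toy, 0.5)
  seqs <- list(A = c(1, 2, 3, 1), B = c(1, 2, 3, 2), C = c(1, 1, 3, 3))
  brute3 <- sum(vapply(1:4, function(s) {
    log(sum(vapply(1:3, function(r)
      toy@freqs[r] * Pa[r, seqs$A[s]] * Pb[r, seqs$B[s]] *
        Pc[r, seqs$C[s]], numeric(1))))
  }, numeric(1)))
  expect_equal(treeLogLik(tr3, msa3, toy), brute3, tolerance = 1e-9)
  # 4-taxon tree: sum over both internal states
  msa4 <- alignmentBlock(c(A = "ABC", B = "BBC", C = "CBA",
                           D = "AAC"))
  tr4 <- readNewickTree("((A:0.2,B:0.3):0.25,C:0.4,D:0.15);")
  s4 <- list(A = c(1, 2, 3), B = c(2, 2, 3), C = c(3, 2, 1),
             D = c(1, 1, 3))
  P <- lapply(c(A = 0.2, B = 0.3, I = 0.25, C = 0.4, D = 0.15),
              function(t) transitionProbability(toy, t))
  brute4 <- sum(vapply(1:3, function(s) {
    tot <- 0
    for (r in 1:3) for (u in 1:3) {
      tot <- tot + toy@freqs[r] * P$I[r, u] * P$A[u, s4$A[s]] *
        P$B[u, s4$B[s]] * P$C[r, s4$C[s]] * P$D[r, s4$D[s]]
    }
    log(tot)
  }, numeric(1)))
  expect_equal(treeLogLik(tr4, msa4, toy), brute4, tolerance = 1e-9)
})

test_that("likelihood obeys the analytic two-taxon limit and gap invariances", {
  # two identical sequences, total branch length -> 0:
  # lnL -> sum(log pi)
  msa <- alignmentBlock(c(A = "ABCAB", B = "ABCAB"))
  tr <- readNewickTree("(A:1e-9,B:1e-9);")
  expected <- sum(log(toy@freqs[c(1, 2, 3, 1, 2)]))
  expect_equal(treeLogLik(tr, msa, toy), expected, tolerance = 1e-5)
  # an all-gap column contributes nothing
  msa_g <- alignmentBlock(c(A = "ABCAB-", B = "ABCAB-"))
  expect_equal(treeLogLik(tr, msa_g, toy), treeLogLik(tr, msa, toy))
  # a leaf without an alignment row is an error
  expect_error(treeLogLik(readNewickTree("(A:1,Z:1);"), msa, toy),
               "leaf without alignment row")
})

test_that("likelihood is invariant to re-rooting (pulley principle)", {
  set.seed(201)
  for (i in 1:20) {
    tr <- random_tree(sample(5:8, 1))
    seqs <- evolveSequences(tr, 60, toy, seed = 300 + i)
    msa <- alignmentBlock(seqs)
    base <- treeLogLik(tr, msa, toy)
    ot <- sample(tr$tip.label, 1)
    rerooted <- ape::root(tr, outgroup = ot, resolve.root = FALSE)
    expect_equal(treeLogLik(rerooted, msa, toy), base,
                 tolerance = 1e-8)
  }
})

test_that("neighbor joining recovers additive trees and the 3-taxon closed form", {
  # additive distances from a known 6-taxon tree -> exact topology
  set.seed(211)
  tr <- random_tree(6)
  D <- ape::cophenetic.phylo(tr)
  nj <- njStartTree(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj), tr)), 0)
  # 3 taxa: three-point formulas
  D3 <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- njStartTree(D3)
  len <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(len[["a"]], (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-9)
  expect_equal(len[["b"]], (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-9)
  expect_equal(len[["c"]], (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-9)
  # determinism on an ultrametric tie-rich matrix
  D4 <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D4) <- 0
  expect_identical(writeNewickTree(njStartTree(D4)),
                   writeNewickTree(njStartTree(D4)))
  expect_error(njStartTree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  Dns <- D3; Dns[1, 2] <- 0.9
  expect_error(njStartTree(Dns), "symmetric")
})

test_that("ML pairwise distance matches a grid-scan oracle on a two-taxon pair", {
  set.seed(221)
  tr2 <- readNewickTree("(A:0.15,B:0.15);")
  seqs <- evolveSequences(tr2, 4000, toy, seed = 17)
  msa <- alignmentBlock(seqs)
  d <- mlPairwiseDistances(msa, toy)["A", "B"]
  # grid-scan oracle over the same objective
  ia <- match(strsplit(as.character(seqs[["A"]]), "")[[1]], toy@states)
  ib <- match(strsplit(as.character(seqs[["B"]]), "")[[1]], toy@states)
  N <- table(factor(ia, levels = 1:3), factor(ib, levels = 1:3))
  grid <- seq(0.005, 2, by = 1e-4)
  ll <- vapply(grid, function(t) {
    P <- transitionProbability(toy, t)
    sum(N * log(toy@freqs * P))
  }, numeric(1))
  expect_equal(d, grid[which.max(ll)], tolerance = 1e-3)
  # identical sequences sit at the lower bound
  msa_id <- alignmentBlock(c(A = "ABCABC", B = "ABCABC"))
  expect_lt(mlPairwiseDistances(msa_id, toy)["A", "B"], 1e-6)
})

test_that("branch-length optimization improves and is a fixed point at the optimum", {
  set.seed(231)
  lls_before <- numeric(); lls_after <- numeric()
  for (i in 1:10) {
    tr <- random_tree(6)
    seqs <- evolveSequences(tr, 150, toy, seed = 400 + i)
    msa <- alignmentBlock(seqs)
    perturbed <- tr
    perturbed$edge.length <- tr$edge.length *
      runif(length(tr$edge.length), 0.3, 3)
    ll0 <- treeLogLik(perturbed, msa, toy)
    opt <- optimizeBranchLengths(perturbed, msa, toy)
    ll1 <- attr(opt, "logLik")
    expect_gte(ll1, ll0 - 1e-9)
    lls_before <- c(lls_before, ll0); lls_after <- c(lls_after, ll1)
    # restarting at the optimum changes nothing appreciably
    opt2 <- optimizeBranchLengths(opt, msa, toy, max_sweeps = 2)
    expect_lt(max(abs(opt2$edge.length - opt$edge.length)), 1e-2)
    expect_lt(abs(attr(opt2, "logLik") - ll1), 1e-3)
  }
  expect_true(all(lls_after >= lls_before - 1e-9))
})

test_that("two-taxon optimized length matches the ML pairwise distance", {
  set.seed(241)
  tr2 <- readNewickTree("(A:0.05,B:0.05);")
  seqs <- evolveSequences(readNewickTree("(A:0.2,B:0.2);"), 3000,
                          toy, seed = 77)
  msa <- alignmentBlock(seqs)
  opt <- optimizeBranchLengths(tr2, msa, toy)
  total <- sum(opt$edge.length)
  d <- mlPairwiseDistances(msa, toy)["A", "B"]
  expect_equal(total, d, tolerance = 1e-3)
})

test_that("NNI search corrects a single perturbed rearrangement", {
  set.seed(251)
  recovered <- 0L
  for (i in 1:5) {
    tr <- random_tree(7, scale = 0.5)
    seqs <- evolveSequences(tr, 1500, toy, seed = 500 + i)
    msa <- alignmentBlock(seqs)
    fit0 <- optimizeBranchLengths(tr, msa, toy)
    # an already-optimal tree is returned unchanged
    same <- nniSearch(fit0, msa, toy, max_rounds = 3)
    expect_equal(as.numeric(ape::dist.topo(same, tr)), 0)
    # perturb by one NNI and search back
    alt <- Get3Atlas:::nni_alternatives(
      fit0, which(fit0$edge[, 2] > length(fit0$tip.label))[1])[[1]]
    found <- nniSearch(alt, msa, toy, max_rounds = 5)
    if (as.numeric(ape::dist.topo(found, tr)) == 0)
      recovered <- recovered + 1L
  }
  expect_gte(recovered, 4L)
})

test_that("bootstrap supports behave and grow with alignment length", {
  # perfectly clade-diagnostic columns -> all true-clade supports 100
  msa <- alignmentBlock(c(A = paste(rep("A", 40), collapse = ""),
                          B = paste(rep("A", 40), collapse = ""),
                          C = paste(rep("C", 40), collapse = ""),
                          D = paste(rep("C", 40), collapse = "")))
  bs <- bootstrapSupports(msa, toy, replicates = 50, seed = 5)
  sup <- nodeSupports(bs)
  expect_true(all(sup[-1] == 100, na.rm = TRUE))
  expect_true(all(sup >= 0 & sup <= 100, na.rm = TRUE))
  # support of a true clade increases with alignment length
  set.seed(261)
  tr <- readNewickTree(
    "((A:0.4,B:0.4):0.08,(C:0.4,D:0.4):0.08,E:0.45);")
  sup_at <- function(n_sites, seed) {
    seqs <- evolveSequences(tr, n_sites, toy, seed = seed)
    m <- alignmentBlock(seqs)
    b <- bootstrapSupports(m, toy, replicates = 50, seed = 9)
    cl <- node_support_of(b, c("A", "B"))
    cl
  }
  node_support_of <- function(phy, tips) {
    n <- ape::getMRCA(phy, tips)
    sets <- Get3Atlas:::node_leafsets(phy)
    if (!setequal(sets[[n]], tips)) return(NA_real_)
    nodeSupports(phy)[n - length(phy$tip.label)]
  }
  s_short <- sup_at(200, 31)
  s_long <- sup_at(2000, 32)
  expect_true(is.na(s_short) || s_long >= s_short)
  expect_equal(s_long, 100, tolerance = 10)
})

test_that("support collapse pins the 70% boundary and its limits", {
  tr <- readNewickTree("(((A:1,B:1)69:1,C:1)70:1,(D:1,E:1)100:1);")
  col <- collapseLowSupport(tr, 70)
  # the 69 node is contracted, the 70 node kept
  expect_equal(col$Nnode, tr$Nnode - 1L)
  labs <- nodeSupports(col)
  expect_true(70 %in% labs)
  expect_false(69 %in% labs)
  expect_false(Get3Atlas::testMonophyly(col, c("A", "B")))
  expect_true(Get3Atlas::testMonophyly(col, c("A", "B", "C")))
  # all supports 100 -> unchanged; threshold 0 -> unchanged;
  # threshold 101 -> star tree
  tr2 <- readNewickTree("(((A:1,B:1)100:1,C:1)100:1,D:1);")
  expect_equal(collapseLowSupport(tr2, 70)$Nnode, tr2$Nnode)
  expect_equal(collapseLowSupport(tr, 0)$Nnode, tr$Nnode)
  expect_equal(collapseLowSupport(tr, 101)$Nnode, 1L)
  # leaf set preserved
  expect_setequal(collapseLowSupport(tr, 101)$tip.label, tr$tip.label)
})

test_that("evolutionary placement recovers pruned leaves and dominates on identity", {
  set.seed(271)
  ok <- 0L
  n_trials <- 50L
  for (i in seq_len(n_trials)) {
    tr <- random_tree(10, scale = 0.4)
    seqs <- evolveSequences(tr, 300, toy, seed = 600 + i)
    msa <- alignmentBlock(seqs)
    drop <- sample(tr$tip.label, 1)
    kept <- ape::drop.tip(tr, drop)
    kept_msa <- alignmentBlock(alignmentRows(msa)[kept$tip.label])
    kept <- optimizeBranchLengths(kept, kept_msa, toy, max_sweeps = 2)
    pl <- epaPlace(alignmentRows(msa)[[drop]], kept, kept_msa, toy)
    # correct edge: the one whose removal separated the dropped leaf;
    # accept the argmax edge or an adjacent edge
    sets <- Get3Atlas:::node_leafsets(tr)
    sibs <- setdiff(
      sets[[tr$edge[which(tr$edge[, 2] ==
                            match(drop, tr$tip.label)), 1]]], drop)
    v <- kept$edge[pl@bestEdge, 2]
    below <- Get3Atlas:::node_leafsets(kept)[[v]]
    u <- kept$edge[pl@bestEdge, 1]
    near <- unique(c(
      below,
      unlist(Get3Atlas:::node_leafsets(kept)[
        kept$edge[kept$edge[, 1] %in% c(u, v), 2]])))
    if (length(intersect(near, sibs)) > 0) ok <- ok + 1L
    expect_equal(nrow(placementTable(pl)), nrow(kept$edge))
  }
  expect_gte(ok / n_trials, 0.9)
})

test_that("a query identical to a leaf places on that leaf's pendant edge", {
  set.seed(281)
  tr <- random_tree(8, scale = 0.4)
  seqs <- evolveSequences(tr, 300, toy, seed = 99)
  msa <- alignmentBlock(seqs)
  fit <- optimizeBranchLengths(tr, msa, toy, max_sweeps = 2)
  pl <- epaPlace(alignmentRows(msa)[["t3"]], fit, msa, toy)
  v <- fit$edge[pl@bestEdge, 2]
  expect_equal(fit$tip.label[v], "t3")
  expect_error(epaPlace(strrep("-", alignmentWidth(msa)), fit, msa,
                        toy), "all gaps")
})

test_that("MRCA rooting is idempotent and metric-preserving", {
  tr <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  r1 <- rootAtMrca(tr, "A", "B")
  expect_true(ape::is.rooted(r1))
  expect_true(Get3Atlas::testMonophyly(r1, c("A", "B")))
  # rooting twice is stable
  r2 <- rootAtMrca(r1, "A", "B")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(r1),
                                         ape::unroot(r2))), 0)
  expect_error(rootAtMrca(tr, "A", "ZZ"), "absent")
  # pairwise path lengths preserved
  set.seed(291)
  for (i in 1:30) {
    phy <- random_tree(sample(5:9, 1))
    ts <- sample(phy$tip.label, 2)
    rooted <- rootAtMrca(phy, ts[1], ts[2])
    expect_setequal(rooted$tip.label, phy$tip.label)
    d0 <- ape::cophenetic.phylo(phy)
    d1 <- ape::cophenetic.phylo(rooted)
    expect_equal(d1[rownames(d0), colnames(d0)], d0,
                 tolerance = 1e-8)
  }
})

test_that("LG likelihood agrees with an independent phylogenetics engine", {
  skip_if_not_installed("phangorn")
  lg <- substitutionModel("LG")
  set.seed(295)
  tr <- random_tree(6, scale = 0.4)
  seqs <- evolveSequences(tr, 120, lg, seed = 55)
  msa <- alignmentBlock(seqs)
  ours <- treeLogLik(tr, msa, lg)
  chars <- strsplit(tolower(alignmentRows(msa)), "")
  pd <- phangorn::phyDat(do.call(rbind, chars), type = "AA")
  fit <- phangorn::pml(tr, pd, model = "LG",
                       bf = unname(lg@freqs))
  expect_equal(ours, as.numeric(fit$logLik), tolerance = 1e-6)
})

test_that("discrete-gamma rates average correctly and recover the uniform limit", {
  rates <- Get3Atlas:::discrete_gamma_rates(0.5, 4)
  expect_equal(mean(rates), 1, tolerance = 1e-12)
  expect_true(all(diff(rates) > 0))
  set.seed(299)
  tr <- random_tree(5, scale = 0.4)
  seqs <- evolveSequences(tr, 80, toy, seed = 61)
  msa <- alignmentBlock(seqs)
  plain <- treeLogLik(tr, msa, toy)
  # a huge shape parameter collapses the mixture onto uniform rates
  expect_equal(treeLogLik(tr, msa, toy, gamma_shape = 1e6), plain,
               tolerance = 1e-6)
  # strong heterogeneity changes the likelihood
  expect_false(isTRUE(all.equal(
    treeLogLik(tr, msa, toy, gamma_shape = 0.3), plain,
    tolerance = 1e-4)))
})
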