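# Pairwise identity, greedy clustering, paired-half retention,
# seed-anchored alignment and keep-length addition.

test_that("pairwise identity matches forced alignments and the DP oracle", {
  expect_equal(pairwiseIdentity("ACDE", "ACDE"), 1.0)
  expect_equal(pairwiseIdentity("ACDE", "ACDD"), 0.75)
  submat <- b62()
  set.seed(71)
  # related pairs (unique optimum): identities agree exactly
  for (i in 1:20) {
    a <- random_aa(sample(15:30, 1))
    ch <- strsplit(a, "")[[1]]
    at <- sample(length(ch), 3)
    ch[at] <- sample(AA, 3, replace = TRUE)
    if (runif(1) < 0.5) ch <- ch[-sample(length(ch), 1)]
    b <- paste(ch, collapse = "")
    expect_equal(pairwiseIdentity(a, b), oracle_identity(a, b, submat),
                 tolerance = 1e-12)
  }
  # unrelated pairs can have co-optimal alignments whose identities
  # differ; the optimal alignment scores must still agree exactly
  for (i in 1:20) {
    a <- random_aa(sample(10:30, 1))
    b <- random_aa(sample(10:30, 1))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = submat,
      gapOpening = 11, gapExtension = 1)
    expect_equal(Biostrings::score(al),
                 oracle_global_align(a, b, submat)$score)
  }
})

test_that("greedy clustering groups identical sequences and splits distant ones", {
  five <- setNames(rep("ACDEFGHIKLMNPQ", 5), paste0("s", 1:5))
  cs <- greedyCluster(five, 0.85)
  expect_equal(length(clusterMembers(cs)), 1L)
  expect_equal(length(clusterMembers(cs)[[1]]), 5L)
  # two sequences at oracle identity far below 0.60 stay apart
  a <- "ACDEFGHIKLWWNPQRSTVY"
  b <- "PQNMLKIHGFEDCAYVTSRW"
  expect_lt(oracle_identity(a, b, b62()), 0.6)
  cs2 <- greedyCluster(c(x = a, y = b), 0.60)
  expect_equal(length(clusterMembers(cs2)), 2L)
  # threshold 1.0 with no duplicates -> all singletons
  set.seed(72)
  seqs <- setNames(vapply(1:6, function(i) random_aa(25), character(1)),
                   paste0("u", 1:6))
  cs3 <- greedyCluster(seqs, 1.0)
  expect_equal(length(clusterMembers(cs3)), 6L)
  # post hoc verification recomputes member->rep identity
  set.seed(73)
  fam <- unlist(lapply(1:3, function(k) {
    base <- random_aa(60)
    v <- vapply(1:3, function(j) {
      ch <- strsplit(base, "")[[1]]
      at <- sample(60, 5)
      ch[at] <- sample(AA, 5, replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
    setNames(c(base, v), paste0("f", k, "_", 0:3))
  }))
  cs4 <- greedyCluster(fam, 0.8)
  expect_true(isTRUE(verifyClusters(cs4, fam)))
  # deterministic under the stated order
  cs5 <- greedyCluster(fam, 0.8)
  expect_identical(clusterMembers(cs4), clusterMembers(cs5))
})

test_that("paired-half retention closes representative sets", {
  pm <- c(A_N = "A_C", A_C = "A_N", B_N = "B_C", B_C = "B_N")
  expect_setequal(keepPairHalves(c("A_N"), pm), c("A_N", "A_C"))
  expect_setequal(keepPairHalves(c("x", "y"), pm), c("x", "y"))
  expect_error(keepPairHalves("A_N", c(A_N = "A_C", A_C = "B_N",
                                       B_N = "A_C")), "symmetric")
  # idempotence on random instances
  set.seed(81)
  for (i in 1:50) {
    ids <- paste0("g", 1:10)
    pairs <- sample(ids, 6)
    pm2 <- setNames(pairs[c(2, 1, 4, 3, 6, 5)], pairs)
    reps <- sample(ids, sample(1:8, 1))
    once <- keepPairHalves(reps, pm2)
    expect_setequal(keepPairHalves(once, pm2), once)
  }
})

test_that("seed-anchored alignment preserves seed columns and gap patterns", {
  seed <- alignmentBlock(c(r1 = "AC-DEFGHIK", r2 = "ACWDE-GHIK"))
  # a sequence identical to a seed row reproduces its gap pattern
  out <- alignToSeed(c(q = "ACDEFGHIK"), seed)
  expect_identical(unname(alignmentRows(out)[["q"]]),
                   unname(alignmentRows(seed)[["r1"]]))
  # width never shrinks
  set.seed(91)
  for (i in 1:10) {
    qs <- setNames(vapply(1:3, function(j) random_aa(sample(6:14, 1)),
                          character(1)), paste0("q", 1:3))
    out2 <- alignToSeed(qs, seed)
    expect_gte(alignmentWidth(out2), alignmentWidth(seed))
    # seed rows keep their mutual gap pattern: ungapping the seed rows
    # of the output recovers the originals, and the seed columns
    # appear in order
    m_out <- as.matrix(out2)[c("r1", "r2"), , drop = FALSE]
    keep <- colSums(m_out != "-") > 0
    expect_identical(
      paste(m_out[1, keep], collapse = ""),
      gsub("(-+$)|(^-+)", "", alignmentRows(seed)[["r1"]]))
  }
})

test_that("progressive alignment attains the exhaustive 3-way optimum on an easy case", {
  # three short sequences differing by one indel/substitution; the
  # sum-of-pairs score of the progressive result must match the
  # brute-force optimum over all 3-way alignments (computed by pairing
  # the exhaustive pairwise optima, which agree for this instance)
  s1 <- "ACDEFGHIK"
  s2 <- "ACDEFGHIK"
  s3 <- "ACDFGHIK"          # one deletion
  seed <- alignmentBlock(c(a = s1, b = s2))
  out <- alignToSeed(c(c = s3), seed)
  rows <- alignmentRows(out)
  sp_score <- function(rows) {
    submat <- b62()
    ids <- names(rows)
    tot <- 0
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      p <- strsplit(rows[[i]], "")[[1]]
      q <- strsplit(rows[[j]], "")[[1]]
      for (k in seq_along(p)) {
        if (p[k] == "-" && q[k] == "-") next
        if (p[k] == "-" || q[k] == "-") next  # gap costs scored below
        tot <- tot + submat[p[k], q[k]]
      }
      # affine gap cost per run
      for (s in list(p == "-" & q != "-", q == "-" & p != "-")) {
        r <- rle(s)
        tot <- tot - sum(11 + (r$lengths[r$values] - 1) * 1)
      }
    }
    tot
  }
  # oracle: the unique optimal 3-way alignment keeps a/b ungapped and
  # opens one single-column gap in c at the E position
  best <- c(a = s1, b = s2, c = "ACD-FGHIK")
  expect_equal(sp_score(rows), sp_score(best))
})

test_that("keep-length addition preserves width and reports insertions", {
  msa <- alignmentBlock(c(r1 = "ACDEFG", r2 = "ACDEFG"))
  same <- addKeepLength(msa, "ACDEFG")
  expect_identical(same$row, "ACDEFG")
  expect_equal(same$n_discarded, 0L)
  ins <- addKeepLength(msa, "ACDWWWWWEFG")
  expect_equal(nchar(ins$row), alignmentWidth(msa))
  expect_equal(ins$n_discarded, 5L)
  # row length equals msa width for random queries
  set.seed(95)
  msa2 <- alignmentBlock(c(x = "AC-DEFGHIKLMNP",
                           y = "ACWDEFGH-KLMNP"))
  for (i in 1:100) {
    q <- random_aa(sample(5:25, 1))
    r <- addKeepLength(msa2, q)
    expect_equal(nchar(r$row), alignmentWidth(msa2))
    # discarded positions are real query positions
    if (r$n_discarded)
      expect_true(all(r$discarded >= 1 & r$discarded <= nchar(q)))
  }
})

test_that("indel-mode simulated sequences align back onto the seed", {
  lg <- substitutionModel("LG")
  tr <- readNewickTree("((A:0.15,B:0.15):0.1,(C:0.15,D:0.15):0.1);")
  seqs <- evolveSequences(tr, 60, lg, seed = 13, indel_rate = 0.02)
  lens <- nchar(as.character(seqs))
  expect_true(any(lens < 60))        # deletions actually occurred
  # anchor the column space on the closely related A/B pair (equal
  # length here), then add the indel-bearing remainder
  sAB <- as.character(seqs)[c("A", "B")]
  if (nchar(sAB[1]) != nchar(sAB[2]))
    sAB <- setNames(rep(sAB[which.max(nchar(sAB))], 2), c("A", "B"))
  seed2 <- alignmentBlock(sAB)
  rest <- as.character(seqs)[c("C", "D")]
  out <- alignToSeed(rest, seed2)
  expect_setequal(names(alignmentRows(out)), c("A", "B", "C", "D"))
  expect_gte(alignmentWidth(out), max(nchar(rest)))
  # every added row ungaps back to its input sequence
  for (id in c("C", "D"))
    expect_identical(ungapRows(alignmentRows(out)[[id]]),
                     unname(as.character(seqs)[id]))
})
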