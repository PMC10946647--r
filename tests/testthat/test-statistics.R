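test_that("the statistic registries are complete", {
  expect_length(dataStatisticNames(), 11L)
  expect_length(inferenceStatisticNames(), 9L)
  expect_setequal(dataStatisticNames(),
                  c("n_invariant", "max_invariant_block",
                    "max_pairwise_diff", "max_variable_block",
                    "min_pairwise_diff", "mean_gc", "var_gc", "theta_w",
                    "tajimas_d", "tajimas_pi", "multinomial_lnl"))
  expect_setequal(inferenceStatisticNames(),
                  c("mean_rf", "rf_q25", "rf_q50", "rf_q75", "rf_q99",
                    "rf_q999", "entropy", "mean_tl", "var_tl"))
  set.seed(1)
  tr <- samplePhyloTree(priorSpec(4, 10, "JC"))
  aln <- simulateAlignment(tr, jcParams(), 30)
  expect_named(dataStatistics(aln), dataStatisticNames())
})

test_that("invariant-site statistics count columns and runs", {
  allSame <- alnFromStrings("ACGTA", "ACGTA", "ACGTA")
  expect_equal(unname(invariantSiteStats(allSame)), c(5, 5, 0))
  # columns: inv, var, inv, inv, var
  mix <- alnFromStrings("AAGGA", "ACGGC", "ACGGC")
  expect_equal(unname(invariantSiteStats(mix)), c(3, 2, 1))
  allVar <- alnFromStrings("AAAA", "CCCC", "GGGG")
  expect_equal(unname(invariantSiteStats(allVar)), c(0, 0, 4))
})

test_that("pairwise differences are scaled mismatch extremes", {
  same <- alnFromStrings("ACGT", "ACGT")
  expect_equal(unname(pairwiseDifferenceStats(same)), c(0, 0))
  # pair mismatch counts {1, 2, 3} over 4 sites
  fx <- alnFromStrings("AAAA", "AAAC", "ACGA")
  pw <- pairwiseDifferenceStats(fx)
  expect_equal(unname(pw), c(0.25, 0.75))
  expect_true(all(pw >= 0 & pw <= 1))
  expect_error(
    pairwiseDifferenceStats(Alignment(matrix("A", 1, 3,
                                             dimnames = list("t1", NULL)))),
    "2 sequences")
})

test_that("GC statistics use per-sequence fractions", {
  allG <- alnFromStrings("GGGG", "GGGG")
  expect_equal(unname(gcStats(allG)), c(1, 0))
  # GC fractions 0.4 and 0.6
  two <- alnFromStrings("GCAAT", "GGCAT")
  expect_equal(unname(gcStats(two)), c(0.5, 0.02))
})

test_that("Watterson's theta divides segregating sites by the harmonic sum", {
  none <- alnFromStrings("AAAA", "AAAA")
  expect_equal(wattersonTheta(none), 0)
  # n = 2: a1 = 1
  n2 <- alnFromStrings("AAAA", "ACGT")
  expect_equal(wattersonTheta(n2), 3)
  # n = 4, 6 segregating sites: a1 = 1 + 1/2 + 1/3
  n4 <- alnFromStrings("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT")
  expect_equal(wattersonTheta(n4), 6 / (1 + 1 / 2 + 1 / 3))
})

test_that("nucleotide diversity averages raw pairwise mismatches", {
  fx <- alnFromStrings("AAAA", "AAAC", "ACGA")
  expect_equal(tajimasPi(fx), 2)
  expect_equal(tajimasPi(alnFromStrings("ACGT", "ACGT")), 0)
  # row permutation invariance
  m <- alignmentMatrix(fx)
  expect_equal(tajimasPi(Alignment(m[c(3, 1, 2), ])), tajimasPi(fx))
})

test_that("Tajima's D matches an independently coded oracle", {
  set.seed(44)
  for (i in 1:10) {
    tr <- sampleBranchLengths(sampleTopology(10), 10)
    aln <- simulateAlignment(tr, jcParams(), 60)
    d <- tajimasD(aln)
    dOracle <- oracleTajimasD(aln)
    if (is.na(dOracle)) expect_true(is.na(d))
    else expect_equal(d, dOracle, tolerance = 1e-10)
  }
  expect_true(is.na(tajimasD(alnFromStrings("AA", "AA", "AA", "AA"))))
  # excess rare variants: singleton-heavy alignment gives D < 0
  rare <- alnFromStrings("AAAAAAAAAA", "CAAAAAAAAA", "AAAAAAAAAA",
                         "AAAAAAAAAA", "AAAAAAAAAA", "AAAAAAAAAA",
                         "AACAAAAAAA", "AAAAAAAAAA", "AAAACAAAAA",
                         "AAAAAAAAAA")
  expect_lt(tajimasD(rare), 0)
})

test_that("multinomial likelihood follows the closed forms", {
  one <- alnFromStrings("AAAA", "CCCC")
  expect_equal(multinomialLikelihood(one), 0)
  # two patterns 50/50 over 100 sites
  m <- matrix("A", 2, 100, dimnames = list(c("t1", "t2"), NULL))
  m[2, 1:50] <- "C"; m[2, 51:100] <- "A"
  expect_equal(multinomialLikelihood(Alignment(m)), 100 * log(0.5))
  # all distinct patterns
  dd <- alnFromStrings("ACGT", "CGTA")
  expect_equal(multinomialLikelihood(dd), 4 * log(1 / 4))
})

test_that("RF distance counts bipartition symmetric differences", {
  set.seed(55)
  t1 <- sampleTopology(4)
  repeat {
    t2 <- sampleTopology(4)
    if (topologyKey(t2) != topologyKey(t1)) break
  }
  expect_equal(rfDistance(t1, t1), 0)
  expect_equal(rfDistance(t1, t2), 2)
  # bound 2(n-3) and agreement with an established implementation
  for (i in 1:20) {
    a <- sampleBranchLengths(sampleTopology(8), 10)
    b <- sampleBranchLengths(sampleTopology(8), 10)
    d <- rfDistance(a, b)
    expect_lte(d, 2 * (8 - 3))
    expect_equal(d, as.numeric(phangorn::RF.dist(a, b)))
  }
  bad <- sampleTopology(5)
  expect_error(rfDistance(sampleTopology(4), bad), "leaf set")
})

test_that("RF summaries follow the sorted-vector quantile convention", {
  set.seed(56)
  base <- sampleBranchLengths(sampleTopology(6), 10)
  repeat {
    alt <- sampleBranchLengths(sampleTopology(6), 10)
    if (rfDistance(base, alt) == 2) break
  }
  same <- rfSummary(rep(list(base), 10))
  expect_true(all(same == 0))
  # alternating trace: enumerate all pairs by brute force
  trees <- rep(list(base, alt), 5)
  s <- rfSummary(trees)
  pairs <- combn(10, 2)
  dref <- sort(apply(pairs, 2, function(ij)
    rfDistance(trees[[ij[1]]], trees[[ij[2]]])))
  qref <- function(q) dref[max(1, ceiling(q * length(dref)))]
  expect_equal(unname(s), c(mean(dref), qref(.25), qref(.5), qref(.75),
                            qref(.99), qref(.999)))
  # order invariance when all pairs are used
  s2 <- rfSummary(trees[c(2:10, 1)])
  expect_equal(s, s2)
  expect_error(rfSummary(list(base)), "2 sampled trees")
})

test_that("topological entropy matches its closed forms", {
  set.seed(57)
  n <- 6
  lnT <- sum(log(seq(1, 2 * n - 5, by = 2)))  # ln((2n-5)!!)
  tr <- sampleTopology(n)
  expect_equal(topologyEntropy(rep(list(tr), 8)), lnT)
  # all unique among m: lnT - ln(m), independent of the trees involved
  trees <- list()
  while (length(trees) < 5) {
    cand <- sampleTopology(n)
    if (!topologyKey(cand) %in% vapply(trees, topologyKey, ""))
      trees <- c(trees, list(cand))
  }
  expect_equal(topologyEntropy(trees), lnT - log(5))
  # 50/50 over two topologies
  expect_equal(topologyEntropy(c(rep(list(trees[[1]]), 4),
                                 rep(list(trees[[2]]), 4))),
               lnT - log(2))
})

test_that("tree-length summaries are simple moments", {
  set.seed(58)
  t1 <- sampleTopology(5); t1$edge.length <- rep(1 / 7, 7)
  t2 <- sampleTopology(5); t2$edge.length <- rep(2 / 7, 7)
  expect_equal(unname(treeLengthStats(list(t1, t2))), c(1.5, 0.5))
  expect_equal(unname(treeLengthStats(rep(list(t1), 5)))[2], 0)
  # prior-only trace: mean tree length ~ (2n-3)/lambda
  spec <- priorSpec(4, 10, "JC")
  trace <- runMCMC(NULL, spec,
                   mcmcConfig(burninIters = 50L, sampleIters = 5000L,
                              thin = 5L, nTaxa = 4), priorOnly = TRUE)
  mt <- treeLengthStats(trace)[["mean_tl"]]
  # mean (2n-3)/lambda = 0.5; generous band for chain autocorrelation
  expect_lt(abs(mt - 0.5), 0.05)
})

test_that("data statistics are invariant to column and row order", {
  set.seed(59)
  tr <- sampleBranchLengths(sampleTopology(6), 10)
  aln <- simulateAlignment(tr, jcParams(), 40)
  m <- alignmentMatrix(aln)
  rowPerm <- Alignment(m[sample(nrow(m)), ])
  s1 <- dataStatistics(aln)
  s2 <- dataStatistics(rowPerm)
  expect_equal(s1, s2)
  # column order affects only the block-run statistics
  colPerm <- Alignment(m[, sample(ncol(m))])
  s3 <- dataStatistics(colPerm)
  keep <- setdiff(dataStatisticNames(),
                  c("max_invariant_block", "max_variable_block"))
  expect_equal(s1[keep], s3[keep])
})

test_that("GC statistics do not depend on the tree at prior scale", {
  # approximate ancillarity: two distinct fixed trees drawn at the prior's
  # scale give indistinguishable GC-statistic distributions (exact
  # tree-independence fails only for extreme depth contrasts, where
  # between-sequence correlation changes the spread of per-sequence GC)
  set.seed(60)
  treeA <- sampleBranchLengths(sampleTopology(8), 10)
  repeat {
    treeB <- sampleBranchLengths(sampleTopology(8), 10)
    if (rfDistance(treeA, treeB) > 0) break
  }
  sim <- function(tree) replicate(300, {
    gcStats(simulateAlignment(tree, jcParams(), 50))
  })
  a <- sim(treeA); b <- sim(treeB)
  pVar <- suppressWarnings(ks.test(a["var_gc", ], b["var_gc", ])$p.value)
  pMean <- suppressWarnings(ks.test(a["mean_gc", ],
                                    b["mean_gc", ])$p.value)
  expect_gt(pVar, 0.01)
  expect_gt(pMean, 0.01)
})
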