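test_that("pattern compression preserves counts and likelihood", {
  m <- matrix("A", 4, 100, dimnames = list(paste0("t", 1:4), NULL))
  m[2, ] <- "C"
  pt <- compressPatterns(Alignment(m))
  expect_equal(ncol(pt@patterns), 1L)
  expect_equal(pt@weights, 100L)

  m2 <- rbind(t1 = c("A", "C", "G"), t2 = c("C", "G", "T"),
              t3 = c("G", "T", "A"), t4 = c("T", "A", "C"))
  pt2 <- compressPatterns(Alignment(m2))
  expect_equal(ncol(pt2@patterns), 3L)
  expect_equal(pt2@weights, rep(1L, 3))

  set.seed(21)
  tr <- sampleBranchLengths(sampleTopology(16), 10)
  aln <- simulateAlignment(tr, jcParams(), 100)
  pt3 <- compressPatterns(aln)
  expect_equal(sum(pt3@weights), 100L)
  # uncompressed table: every column its own pattern
  codes <- phyloppc:::alnCodes(aln)
  raw <- new("PatternTable", patterns = codes,
             weights = rep(1L, ncol(codes)), taxa = rownames(codes))
  expect_lt(abs(logLikelihood(tr, jcParams(), pt3) -
                logLikelihood(tr, jcParams(), raw)), 1e-10)
})

test_that("2-sequence JC site likelihood matches the closed form", {
  d <- 0.3
  tr <- twoTaxonTree(d)
  alnSame <- alnFromStrings("A", "A")
  pMatch <- 0.25 + 0.75 * exp(-4 * d / 3)
  expect_equal(logLikelihood(tr, jcParams(), alnSame),
               log(0.25 * pMatch), tolerance = 1e-12)
  alnDiff <- alnFromStrings("A", "G")
  pMis <- 0.25 - 0.25 * exp(-4 * d / 3)
  expect_equal(logLikelihood(tr, jcParams(), alnDiff),
               log(0.25 * pMis), tolerance = 1e-12)
})

test_that("pruning equals brute-force state enumeration", {
  set.seed(8)
  for (flavor in c("JC", "GTR_GI")) {
    spec <- priorSpec(4, 10, flavor)
    tr <- samplePhyloTree(spec)
    p <- drawModelParams(spec)
    aln <- simulateAlignment(tr, p, 12)
    ll <- logLikelihood(tr, p, aln)
    expect_equal(ll, oracleBruteLogLik(tr, p, aln),
                 tolerance = 1e-8)
  }
  # 5 taxa, JC
  spec5 <- priorSpec(5, 10, "JC")
  tr5 <- samplePhyloTree(spec5)
  aln5 <- simulateAlignment(tr5, jcParams(), 10)
  expect_equal(logLikelihood(tr5, jcParams(), aln5),
               oracleBruteLogLik(tr5, jcParams(), aln5),
               tolerance = 1e-8)
  # cross-check against an established pruning implementation
  pd <- phangorn::as.phyDat(alignmentMatrix(aln5))
  expect_equal(logLikelihood(tr5, jcParams(), aln5),
               phangorn::pml(ape::unroot(tr5), pd)$logLik,
               tolerance = 1e-6)
})

test_that("zero-length trees give vanishing likelihood on variable data", {
  tr <- sampleTopology(4)
  tr$edge.length <- rep(1e-12, 5)
  aln <- alnFromStrings("AAAA", "AAAA", "AAAA", "ACGT")
  expect_lt(logLikelihood(tr, jcParams(), aln), -50)
})

test_that("taxon mismatches are rejected", {
  set.seed(9)
  tr <- samplePhyloTree(priorSpec(4, 10, "JC"))
  aln <- simulateAlignment(tr, jcParams(), 10)
  tr$tip.label[1] <- "zz"
  expect_error(logLikelihood(tr, jcParams(), aln), "taxa differ")
})

test_that("tree moves keep the state valid and NNI steps are local", {
  set.seed(14)
  spec <- priorSpec(8, 10, "JC")
  tr <- samplePhyloTree(spec)
  p <- jcParams()
  cur <- tr
  for (i in 1:200) {
    mv <- sample(c("nni", "spr", "blScale"), 1)
    out <- applyMove(cur, p, mv)
    nxt <- out$tree
    # structural validity: 2n-3 edges, every non-root node has one parent,
    # root keeps its trifurcation
    expect_equal(nrow(nxt$edge), 13)
    expect_equal(sort(nxt$edge[, 2]), c(1:8, 10:14))
    expect_equal(sum(nxt$edge[, 1] == 9), 3)
    expect_true(all(nxt$edge.length > 0))
    if (mv == "nni") expect_lte(rfDistance(cur, nxt), 2)
    cur <- nxt
  }
})

test_that("scale moves report the scale-move Jacobian", {
  set.seed(15)
  tr <- samplePhyloTree(priorSpec(5, 10, "JC"))
  p <- jcParams()
  for (i in 1:50) {
    out <- applyMove(tr, p, "blScale", tuning = 2)
    changed <- which(abs(out$tree$edge.length - tr$edge.length) > 0)
    expect_length(changed, 1L)
    mult <- out$tree$edge.length[changed] / tr$edge.length[changed]
    expect_equal(out$logHastings, log(mult), tolerance = 1e-12)
  }
})

test_that("simplex and probability moves stay on their supports", {
  set.seed(16)
  spec <- priorSpec(4, 10, "GTR_GI")
  tr <- samplePhyloTree(spec)
  p <- drawModelParams(spec)
  for (mv in c("betaSimplexPi", "dirSimplexPi", "betaSimplexEr",
               "dirSimplexEr", "betaProbPinv")) {
    for (i in 1:50) {
      out <- applyMove(tr, p, mv)
      if (!is.finite(out$logHastings)) next
      pp <- out$params
      expect_lt(abs(sum(baseFreqs(pp)) - 1), 1e-12)
      expect_lt(abs(sum(exchangeabilities(pp)) - 1), 1e-12)
      expect_true(all(baseFreqs(pp) > 0))
      expect_true(all(exchangeabilities(pp) > 0))
      expect_true(pInv(pp) > 0 && pInv(pp) < 1)
      p <- pp
    }
  }
})

test_that("prior-only chains recover the joint prior (JC)", {
  set.seed(17)
  spec <- priorSpec(4, 10, "JC")
  cfg <- mcmcConfig(burninIters = 100L, sampleIters = 20000L, thin = 10L,
                    nTaxa = 4)
  trace <- runMCMC(NULL, spec, cfg, priorOnly = TRUE)
  expect_equal(nSamples(trace), 2000L)
  # branch-length marginal: Exponential(10) mean 0.1
  bl <- unlist(lapply(sampledTrees(trace), function(t) t$edge.length))
  expect_lt(abs(mean(bl) - 0.1), 0.01)
  # the 3 topologies uniform
  keys <- vapply(sampledTrees(trace), topologyKey, "")
  tab <- table(keys)
  expect_equal(length(tab), 3L)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("prior-only chains recover the parameter priors (GTR+G+I)", {
  set.seed(18)
  spec <- priorSpec(4, 10, "GTR_GI")
  cfg <- mcmcConfig(burninIters = 200L, sampleIters = 25000L, thin = 5L,
                    nTaxa = 4, modelFlavor = "GTR_GI")
  trace <- runMCMC(NULL, spec, cfg, priorOnly = TRUE)
  pm <- sampledParams(trace)
  expect_equal(nrow(pm), 5000L)
  idx <- seq(1, nrow(pm), by = 10)  # thin further against autocorrelation
  expect_gt(ks.test(pm[idx, "shape"], "pexp", 0.05)$p.value, 0.01)
  expect_gt(ks.test(pm[idx, "pinv"], "pbeta", 10, 20)$p.value, 0.01)
  # Dirichlet(1,1,1,1) marginal is Beta(1,3); Dirichlet(1^6) is Beta(1,5)
  expect_gt(ks.test(pm[idx, "pi_A"], "pbeta", 1, 3)$p.value, 0.01)
  expect_gt(ks.test(pm[idx, "er_AC"], "pbeta", 1, 5)$p.value, 0.01)
  bl <- unlist(lapply(sampledTrees(trace)[idx],
                      function(t) t$edge.length))
  expect_gt(ks.test(bl, "pexp", 10)$p.value, 0.01)
})

test_that("strong phylogenetic signal recovers the true topology", {
  set.seed(19)
  # 4-taxon tree with a long internal branch and short terminals
  tr <- structure(list(
    edge = cbind(c(5L, 5L, 5L, 6L, 6L), c(1L, 2L, 6L, 3L, 4L)),
    edge.length = c(0.05, 0.05, 0.5, 0.05, 0.05),
    tip.label = paste0("t", 1:4), Nnode = 2L), class = "phylo")
  trueKey <- topologyKey(tr)
  spec <- priorSpec(4, 10, "JC")
  cfg <- mcmcConfig(burninIters = 100L, sampleIters = 500L, thin = 10L,
                    nTaxa = 4)
  hits <- 0L
  for (rep in 1:20) {
    aln <- simulateAlignment(tr, jcParams(), 1000)
    trace <- runMCMC(aln, spec, cfg)
    keys <- vapply(sampledTrees(trace), topologyKey, "")
    if (names(which.max(table(keys))) == trueKey) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("empty sampling returns an empty trace and chains are seeded", {
  spec <- priorSpec(4, 10, "JC")
  set.seed(20)
  tr <- samplePhyloTree(spec)
  aln <- simulateAlignment(tr, jcParams(), 30)
  cfg0 <- mcmcConfig(burninIters = 10L, sampleIters = 0L, thin = 1L,
                     nTaxa = 4)
  expect_equal(nSamples(runMCMC(aln, spec, cfg0)), 0L)

  cfg <- mcmcConfig(burninIters = 50L, sampleIters = 200L, thin = 10L,
                    nTaxa = 4)
  set.seed(77); trA <- runMCMC(aln, spec, cfg)
  set.seed(77); trB <- runMCMC(aln, spec, cfg)
  expect_identical(sampledParams(trA), sampledParams(trB))
  expect_identical(logPosterior(trA), logPosterior(trB))
  expect_identical(lapply(sampledTrees(trA), `[[`, "edge"),
                   lapply(sampledTrees(trB), `[[`, "edge"))
})

test_that("JC analyses reject substitution-parameter moves", {
  spec <- priorSpec(4, 10, "JC")
  w <- defaultMoveWeights(4, "GTR_GI")
  cfg <- mcmcConfig(moveWeights = w)
  set.seed(1)
  tr <- samplePhyloTree(spec)
  aln <- simulateAlignment(tr, jcParams(), 10)
  expect_error(runMCMC(aln, spec, cfg), "not applicable")
})

test_that("trace serialization round-trips", {
  set.seed(23)
  spec <- priorSpec(5, 10, "JC")
  tr <- samplePhyloTree(spec)
  aln <- simulateAlignment(tr, jcParams(), 40)
  trace <- runMCMC(aln, spec, mcmcConfig(burninIters = 20L,
                                         sampleIters = 100L, thin = 10L,
                                         nTaxa = 5))
  pre <- file.path(tempdir(), "tracecheck")
  writeTrace(trace, pre)
  back <- readTrace(pre)
  expect_equal(nSamples(back), nSamples(trace))
  expect_equal(back@params[, "treeLength"],
               trace@params[, "treeLength"], tolerance = 1e-6,
               ignore_attr = TRUE)
  rf <- mapply(rfDistance, sampledTrees(back), sampledTrees(trace))
  expect_true(all(rf == 0))
})
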