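miniTrace <- function(seed = 30, nTaxa = 5, nSites = 30) {
  set.seed(seed)
  spec <- priorSpec(nTaxa, 10, "JC")
  tr <- samplePhyloTree(spec)
  aln <- simulateAlignment(tr, jcParams(), nSites)
  list(spec = spec, aln = aln,
       trace = runMCMC(aln, spec,
                       mcmcConfig(burninIters = 50L, sampleIters = 200L,
                                  thin = 10L, nTaxa = nTaxa)))
}

test_that("predictive sets respect the dimensional contract", {
  mt <- miniTrace()
  pset <- posteriorPredictive(mt$trace, 30, 7)
  expect_equal(length(predictiveAlignments(pset)), 7L)
  expect_true(all(vapply(predictiveAlignments(pset), nTaxa, 0L) == 5L))
  expect_true(all(vapply(predictiveAlignments(pset), nSites, 0L) == 30L))
  expect_equal(predictiveSource(pset), "posterior")
  expect_equal(length(predictiveThetas(pset)), 7L)
  expect_error(posteriorPredictive(new("PosteriorTrace",
    trees = list(), params = matrix(0, 0, 11), logPosterior = numeric(),
    iteration = integer(), acceptance = data.frame(), config = NULL),
    30, 5), "empty")
})

test_that("the three sources share one simulation kernel", {
  mt <- miniTrace(31)
  tr1 <- sampledTrees(mt$trace)[[1]]
  # a single-draw posterior predictive equals direct simulation under the
  # same theta and seed
  oneTrace <- new("PosteriorTrace", trees = list(tr1),
                  params = mt$trace@params[1, , drop = FALSE],
                  logPosterior = mt$trace@logPosterior[1],
                  iteration = 1L, acceptance = mt$trace@acceptance,
                  config = NULL)
  set.seed(5)
  ps <- posteriorPredictive(oneTrace, 30, 1)
  set.seed(5)
  direct <- simulateAlignment(tr1, jcParams(), 30)
  expect_identical(alignmentMatrix(predictiveAlignments(ps)[[1]]),
                   alignmentMatrix(direct))
  # fixed-theta: same via fixedPredictive
  set.seed(5)
  fx <- fixedPredictive(tr1, jcParams(), 30, 1)
  expect_identical(alignmentMatrix(predictiveAlignments(fx)[[1]]),
                   alignmentMatrix(direct))
})

test_that("prior-chain posterior predictive matches prior predictive", {
  set.seed(32)
  spec <- priorSpec(5, 10, "JC")
  trace <- runMCMC(NULL, spec,
                   mcmcConfig(burninIters = 100L, sampleIters = 30000L,
                              thin = 50L, nTaxa = 5), priorOnly = TRUE)
  psPost <- posteriorPredictive(trace, 20, 600)
  psPrior <- priorPredictive(spec, 20, 600)
  tl <- function(ps) vapply(ps@trees, function(t) sum(t$edge.length), 0)
  expect_gt(suppressWarnings(
    ks.test(tl(psPost), tl(psPrior))$p.value), 0.01)
  gc <- function(ps) vapply(predictiveAlignments(ps),
                            function(a) gcStats(a)[["mean_gc"]], 0)
  expect_lt(abs(mean(gc(psPost)) - mean(gc(psPrior))), 0.02)
  expect_lt(abs(mean(gc(psPrior)) - 0.5), 0.01)  # JC symmetry
})

test_that("fixed-theta sets remove parameter uncertainty", {
  set.seed(34)
  spec <- priorSpec(6, 10, "JC")
  theta <- list(tree = samplePhyloTree(spec), params = jcParams())
  fx <- fixedPredictive(theta$tree, theta$params, 40, 300)
  expect_true(all(vapply(fx@trees, function(t)
    identical(t$edge.length, theta$tree$edge.length), TRUE)))
  nInv <- function(ps) vapply(predictiveAlignments(ps), function(a)
    invariantSiteStats(a)[["n_invariant"]], 0)
  vFixed <- var(nInv(fx))
  pp <- priorPredictive(spec, 40, 300)
  vPrior <- var(nInv(pp))
  expect_lte(vFixed, vPrior)
  # seed determinism
  set.seed(8); s1 <- fixedPredictive(theta$tree, theta$params, 10, 3)
  set.seed(8); s2 <- fixedPredictive(theta$tree, theta$params, 10, 3)
  expect_identical(lapply(predictiveAlignments(s1), alignmentMatrix),
                   lapply(predictiveAlignments(s2), alignmentMatrix))
  # S = 0 is allowed
  expect_length(predictiveAlignments(priorPredictive(spec, 10, 0)), 0L)
})

test_that("predictive sets serialize with a manifest", {
  mt <- miniTrace(35)
  pset <- posteriorPredictive(mt$trace, 30, 4)
  d <- file.path(tempdir(), "psetcheck")
  writePredictiveSet(pset, d)
  expect_true(file.exists(file.path(d, "manifest.tsv")))
  man <- read.table(file.path(d, "manifest.tsv"), header = TRUE,
                    sep = "\t")
  expect_equal(nrow(man), 4L)
  back <- readFasta(file.path(d, man$dataset[2]))
  expect_identical(alignmentMatrix(back),
                   alignmentMatrix(predictiveAlignments(pset)[[2]]))
})
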