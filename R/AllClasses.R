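#' @import methods
#' @importFrom stats rexp rbeta rgamma runif dexp dbeta pgamma qgamma var
#'   median sd ks.test chisq.test cor quantile setNames
#' @importFrom utils write.table read.table head tail
#' @useDynLib phyloppc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setOldClass("phylo")
setOldClass("multiPhylo")

NUC <- c("A", "C", "G", "T")
ER_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Prior specification for a phylogenetic substitution model
#'
#' Bundles the hyperparameters of the joint prior over tree topology, branch
#' lengths and substitution-model parameters: an unrooted-uniform topology
#' prior, i.i.d. Exponential(\code{blRate}) branch lengths, and (for the
#' GTR+Gamma+I flavor) Dirichlet priors on base frequencies and
#' exchangeabilities, an Exponential prior on the Gamma shape and a Beta
#' prior on the proportion of invariable sites.
#'
#' @slot nTaxa number of taxa (>= 4).
#' @slot blRate rate of the Exponential branch-length prior (mean 1/rate,
#'   in expected substitutions per site).
#' @slot modelFlavor \code{"JC"} or \code{"GTR_GI"}.
#' @slot piAlpha Dirichlet concentration for base frequencies (length 4).
#' @slot erAlpha Dirichlet concentration for exchangeabilities (length 6).
#' @slot shapeRate rate of the Exponential prior on the Gamma shape.
#' @slot pinvBeta (alpha, beta) of the Beta prior on the invariable-site
#'   proportion.
#' @export
setClass("PriorSpec",
  representation(
    nTaxa = "integer",
    blRate = "numeric",
    modelFlavor = "character",
    piAlpha = "numeric",
    erAlpha = "numeric",
    shapeRate = "numeric",
    pinvBeta = "numeric"
  )
)

setValidity("PriorSpec", function(object) {
  msg <- character()
  if (length(object@nTaxa) != 1L || is.na(object@nTaxa) || object@nTaxa < 4L)
    msg <- c(msg, "nTaxa must be a single integer >= 4")
  if (length(object@blRate) != 1L || !is.finite(object@blRate) ||
      object@blRate <= 0)
    msg <- c(msg, "blRate must be a single positive number")
  if (!object@modelFlavor %in% c("JC", "GTR_GI"))
    msg <- c(msg, "modelFlavor must be 'JC' or 'GTR_GI'")
  if (length(object@piAlpha) != 4L || any(object@piAlpha <= 0))
    msg <- c(msg, "piAlpha must be 4 strictly positive values")
  if (length(object@erAlpha) != 6L || any(object@erAlpha <= 0))
    msg <- c(msg, "erAlpha must be 6 strictly positive values")
  if (length(object@shapeRate) != 1L || object@shapeRate <= 0)
    msg <- c(msg, "shapeRate must be a single positive number")
  if (length(object@pinvBeta) != 2L || any(object@pinvBeta <= 0))
    msg <- c(msg, "pinvBeta must be 2 strictly positive values")
  if (length(msg)) msg else TRUE
})

#' Construct a PriorSpec
#'
#' Defaults follow the standard prior table used throughout the package:
#' Dirichlet(1,1,1,1) base frequencies, Dirichlet(1,...,1) exchangeabilities,
#' Exponential(0.05) Gamma shape and Beta(10, 20) invariable-site proportion.
#'
#' @param nTaxa number of taxa (>= 4).
#' @param blRate Exponential rate for branch lengths (e.g. 10 for mean 0.1).
#' @param modelFlavor \code{"JC"} or \code{"GTR_GI"}.
#' @param piAlpha,erAlpha,shapeRate,pinvBeta prior hyperparameters; see
#'   class documentation.
#' @return A \code{PriorSpec} object.
#' @examples
#' priorSpec(16, blRate = 10, modelFlavor = "JC")
#' @export
priorSpec <- function(nTaxa, blRate = 10, modelFlavor = c("JC", "GTR_GI"),
                      piAlpha = rep(1, 4), erAlpha = rep(1, 6),
                      shapeRate = 0.05, pinvBeta = c(10, 20)) {
  modelFlavor <- match.arg(modelFlavor)
  new("PriorSpec", nTaxa = as.integer(nTaxa), blRate = as.numeric(blRate),
      modelFlavor = modelFlavor, piAlpha = as.numeric(piAlpha),
      erAlpha = as.numeric(erAlpha), shapeRate = as.numeric(shapeRate),
      pinvBeta = as.numeric(pinvBeta))
}

#' Substitution-model parameters
#'
#' A concrete parameter value for the JC or GTR+Gamma+I substitution model:
#' equilibrium base frequencies (order A, C, G, T), exchangeabilities (order
#' AC, AG, AT, CG, CT, GT), the Gamma shape for among-site rate variation
#' and the proportion of invariable sites. JC fixes pi = 1/4,
#' er = 1/6, all site rates 1 and pinv = 0.
#'
#' @slot pi equilibrium base frequencies, a 4-simplex.
#' @slot er exchangeabilities, a 6-simplex.
#' @slot shape Gamma shape parameter (> 0).
#' @slot pinv proportion of invariable sites in [0, 1).
#' @slot nCategories number of discrete Gamma rate categories.
#' @export
setClass("ModelParams",
  representation(
    pi = "numeric",
    er = "numeric",
    shape = "numeric",
    pinv = "numeric",
    nCategories = "integer"
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  if (length(object@pi) != 4L || any(object@pi <= 0))
    msg <- c(msg, "pi must be 4 strictly positive frequencies")
  else if (abs(sum(object@pi) - 1) > 1e-12)
    msg <- c(msg, "pi must sum to 1 (tolerance 1e-12)")
  if (length(object@er) != 6L || any(object@er <= 0))
    msg <- c(msg, "er must be 6 strictly positive exchangeabilities")
  else if (abs(sum(object@er) - 1) > 1e-12)
    msg <- c(msg, "er must sum to 1 (tolerance 1e-12)")
  if (length(object@shape) != 1L || object@shape <= 0)
    msg <- c(msg, "shape must be a single positive number")
  if (length(object@pinv) != 1L || object@pinv < 0 || object@pinv >= 1)
    msg <- c(msg, "pinv must lie in [0, 1)")
  if (length(object@nCategories) != 1L || object@nCategories < 1L)
    msg <- c(msg, "nCategories must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct ModelParams
#'
#' @param pi base frequencies (A, C, G, T), summing to 1.
#' @param er exchangeabilities (AC, AG, AT, CG, CT, GT), summing to 1.
#' @param shape Gamma shape parameter.
#' @param pinv proportion of invariable sites.
#' @param nCategories number of discrete Gamma categories (default 4).
#' @return A \code{ModelParams} object.
#' @examples
#' jcParams()
#' modelParams(pi = c(.1, .2, .3, .4), er = rep(1/6, 6), shape = 0.5,
#'             pinv = 0.3)
#' @export
modelParams <- function(pi = rep(0.25, 4), er = rep(1 / 6, 6), shape = 1,
                        pinv = 0, nCategories = 4L) {
  new("ModelParams", pi = as.numeric(pi), er = as.numeric(er),
      shape = as.numeric(shape), pinv = as.numeric(pinv),
      nCategories = as.integer(nCategories))
}

#' @rdname modelParams
#' @export
jcParams <- function() modelParams(nCategories = 1L)

#' Multiple sequence alignment of simulated DNA
#'
#' A taxa-by-sites character matrix over the strict alphabet {A, C, G, T}.
#' Simulated alignments contain no gaps or ambiguity codes by construction,
#' and the class enforces that.
#'
#' @slot seqs character matrix; rownames are taxon labels.
#' @export
setClass("Alignment", representation(seqs = "matrix"))

setValidity("Alignment", function(object) {
  m <- object@seqs
  msg <- character()
  if (!is.character(m)) msg <- c(msg, "seqs must be a character matrix")
  else {
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      msg <- c(msg, "rownames must be unique taxon labels")
    if (!all(m %in% NUC))
      msg <- c(msg, "alignment characters must be A, C, G or T")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Alignment
#'
#' @param seqs character matrix (taxa x sites) over A/C/G/T, with unique
#'   rownames, or an integer matrix with codes 1..4 (A=1, C=2, G=3, T=4).
#' @return An \code{Alignment}.
#' @export
Alignment <- function(seqs) {
  if (is.numeric(seqs)) {
    codes <- seqs
    seqs <- matrix(NUC[codes], nrow = nrow(codes),
                   dimnames = dimnames(codes))
  }
  new("Alignment", seqs = seqs)
}

#' Compressed site-pattern table
#'
#' Distinct alignment columns with multiplicities; the pruning likelihood on
#' the table equals the likelihood on the raw alignment, at a fraction of
#' the cost.
#'
#' @slot patterns integer matrix (taxa x patterns), codes 1..4.
#' @slot weights integer pattern counts, summing to the number of sites.
#' @slot taxa taxon labels, aligned with pattern rows.
#' @export
setClass("PatternTable",
  representation(patterns = "matrix", weights = "integer",
                 taxa = "character"))

setValidity("PatternTable", function(object) {
  msg <- character()
  if (ncol(object@patterns) != length(object@weights))
    msg <- c(msg, "one weight per pattern required")
  if (any(object@weights < 1L))
    msg <- c(msg, "weights must be positive")
  if (nrow(object@patterns) != length(object@taxa))
    msg <- c(msg, "one taxon label per pattern row required")
  if (length(msg)) msg else TRUE
})

#' MCMC run configuration
#'
#' @slot burninIters number of burn-in iterations.
#' @slot sampleIters number of sampling iterations.
#' @slot thin sampling interval (a state is recorded every \code{thin}
#'   iterations).
#' @slot tuneInterval iterations between auto-tuning updates.
#' @slot tuneDuringSampling whether auto-tuning continues after burn-in.
#' @slot moveWeights named nonnegative move weights; per iteration,
#'   \code{round(sum(moveWeights))} single-move updates are attempted, each
#'   move drawn with probability proportional to its weight.
#' @export
setClass("MCMCConfig",
  representation(
    burninIters = "integer",
    sampleIters = "integer",
    thin = "integer",
    tuneInterval = "integer",
    tuneDuringSampling = "logical",
    moveWeights = "numeric"
  )
)

setValidity("MCMCConfig", function(object) {
  msg <- character()
  if (object@burninIters < 0L) msg <- c(msg, "burninIters must be >= 0")
  if (object@sampleIters < 0L) msg <- c(msg, "sampleIters must be >= 0")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@tuneInterval < 1L) msg <- c(msg, "tuneInterval must be >= 1")
  w <- object@moveWeights
  if (is.null(names(w)) || any(!names(w) %in% MOVE_NAMES))
    msg <- c(msg, paste("moveWeights names must be among:",
                        paste(MOVE_NAMES, collapse = ", ")))
  if (any(w < 0)) msg <- c(msg, "moveWeights must be nonnegative")
  if (sum(w) <= 0) msg <- c(msg, "at least one move weight must be positive")
  if (length(msg)) msg else TRUE
})

MOVE_NAMES <- c("nni", "spr", "blScale", "betaSimplexPi", "dirSimplexPi",
                "betaSimplexEr", "dirSimplexEr", "scaleShape", "betaProbPinv")

#' Default move weights
#'
#' The standard move schedule: NNI and branch-length scaling each weighted by
#' the number of taxa, SPR by a tenth of it; GTR+Gamma+I analyses add
#' simplex, scale and probability moves for the substitution-model
#' parameters (weights 2, 1, 3, 1.5, 2 and 2). JC analyses use only the
#' first three moves.
#'
#' @param nTaxa number of taxa.
#' @param modelFlavor \code{"JC"} or \code{"GTR_GI"}.
#' @return Named numeric vector of move weights.
#' @export
defaultMoveWeights <- function(nTaxa, modelFlavor = c("JC", "GTR_GI")) {
  modelFlavor <- match.arg(modelFlavor)
  w <- c(nni = nTaxa, spr = 0.1 * nTaxa, blScale = nTaxa)
  if (modelFlavor == "GTR_GI")
    w <- c(w, betaSimplexPi = 2, dirSimplexPi = 1, betaSimplexEr = 3,
           dirSimplexEr = 1.5, scaleShape = 2, betaProbPinv = 2)
  w
}

#' Construct an MCMCConfig
#'
#' Defaults mirror the standard analysis settings: burn-in of 200
#' iterations, 10,000 sampling iterations with auto-tuning every 200
#' iterations during both phases, thinned so that roughly 200 states are
#' retained.
#'
#' @param burninIters,sampleIters,thin,tuneInterval,tuneDuringSampling see
#'   class slots.
#' @param moveWeights named move-weight vector; see
#'   \code{\link{defaultMoveWeights}}.
#' @param nTaxa,modelFlavor used to build default move weights when
#'   \code{moveWeights} is missing.
#' @return An \code{MCMCConfig}.
#' @export
mcmcConfig <- function(burninIters = 200L, sampleIters = 10000L,
                       thin = max(1L, as.integer(sampleIters / 200)),
                       tuneInterval = 200L, tuneDuringSampling = TRUE,
                       moveWeights = NULL, nTaxa = NULL,
                       modelFlavor = "JC") {
  if (is.null(moveWeights)) {
    if (is.null(nTaxa))
      stop("either moveWeights or nTaxa must be supplied")
    moveWeights <- defaultMoveWeights(nTaxa, modelFlavor)
  }
  new("MCMCConfig", burninIters = as.integer(burninIters),
      sampleIters = as.integer(sampleIters), thin = as.integer(thin),
      tuneInterval = as.integer(tuneInterval),
      tuneDuringSampling = isTRUE(tuneDuringSampling),
      moveWeights = moveWeights)
}

#' Posterior trace from a phylogenetic MCMC run
#'
#' Thinned samples of (tree, substitution-model parameters, log posterior),
#' plus per-move acceptance tallies.
#'
#' @slot trees list of sampled \code{phylo} trees.
#' @slot params numeric matrix of sampled scalar parameters, one row per
#'   sample (columns pi_A..pi_T, er_AC..er_GT, shape, pinv, treeLength).
#' @slot logPosterior log posterior density (up to a constant) per sample.
#' @slot iteration iteration index of each sample.
#' @slot acceptance data.frame with columns move, proposed, accepted.
#' @slot config the \code{MCMCConfig} used.
#' @export
setClass("PosteriorTrace",
  representation(
    trees = "list",
    params = "matrix",
    logPosterior = "numeric",
    iteration = "integer",
    acceptance = "data.frame",
    config = "ANY"
  )
)

setValidity("PosteriorTrace", function(object) {
  n <- length(object@trees)
  msg <- character()
  if (nrow(object@params) != n || length(object@logPosterior) != n ||
      length(object@iteration) != n)
    msg <- c(msg, "trees, params, logPosterior and iteration must align")
  if (n > 0 && any(!is.finite(object@logPosterior)))
    msg <- c(msg, "logPosterior must be finite for every sample")
  if (length(msg)) msg else TRUE
})

#' Predictive dataset collection
#'
#' S alignments simulated under parameter draws from one of three sources:
#' the posterior (posterior predictive), the prior (prior predictive), or a
#' single fixed parameter value (the fixed-parameter null used by
#' frequentist-style checks).
#'
#' @slot source \code{"posterior"}, \code{"prior"} or \code{"fixed"}.
#' @slot alignments list of S \code{Alignment} objects.
#' @slot trees list of the S generating trees.
#' @slot params list of the S generating \code{ModelParams}.
#' @export
setClass("PredictiveSet",
  representation(source = "character", alignments = "list",
                 trees = "list", params = "list"))

setValidity("PredictiveSet", function(object) {
  msg <- character()
  if (!object@source %in% c("posterior", "prior", "fixed"))
    msg <- c(msg, "source must be posterior, prior or fixed")
  S <- length(object@alignments)
  if (length(object@trees) != S || length(object@params) != S)
    msg <- c(msg, "alignments, trees and params must have equal length")
  if (length(msg)) msg else TRUE
})
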