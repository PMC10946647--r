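# Bayesian MCMC over topology, branch lengths and substitution-model
# parameters: pattern compression, pruning likelihood and the
# Metropolis-Hastings sampler (numerical core in src/mcmc.cpp).

#' Compress an alignment into distinct site patterns
#'
#' The pruning likelihood is a product over sites of quantities that depend
#' only on the site's column pattern, so distinct columns are collapsed and
#' weighted by their multiplicities.
#'
#' @param aln an \code{\link{Alignment}}.
#' @return A \code{PatternTable}.
#' @examples
#' tr <- sampleBranchLengths(sampleTopology(4), 10)
#' compressPatterns(simulateAlignment(tr, jcParams(), 50))
#' @export
compressPatterns <- function(aln) {
  stopifnot(is(aln, "Alignment"))
  m <- alignmentMatrix(aln)
  codes <- matrix(match(m, NUC), nrow = nrow(m))
  n <- nrow(codes)
  if (n <= 26L) {
    key <- as.numeric(crossprod(4^(seq_len(n) - 1), codes - 1L))
  } else {
    key <- apply(codes, 2L, paste, collapse = ",")
  }
  first <- !duplicated(key)
  idx <- match(key, key[first])
  new("PatternTable",
      patterns = codes[, first, drop = FALSE],
      weights = tabulate(idx, nbins = sum(first)),
      taxa = rownames(m))
}

# order pattern rows to match a tree's tip labels
orderPatterns <- function(pt, tipLabels) {
  ord <- match(tipLabels, pt@taxa)
  if (anyNA(ord))
    stop("tree tips and alignment taxa differ: missing ",
         paste(setdiff(tipLabels, pt@taxa), collapse = ", "))
  pt@patterns[ord, , drop = FALSE]
}

#' Phylogenetic log likelihood by Felsenstein pruning
#'
#' Computes the log likelihood of the compressed site patterns on a tree
#' under JC or GTR+Gamma+I, pruning from the tree's root node (the result
#' is root-invariant for these time-reversible models). With invariable
#' sites, the invariant class contributes a frequency-weighted indicator of
#' column constancy through its zero-rate transition matrix.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param params a \code{ModelParams}.
#' @param data a \code{PatternTable} or an \code{Alignment} (compressed
#'   internally).
#' @return The log likelihood (a large negative number stands in for a
#'   zero-likelihood configuration).
#' @examples
#' tr <- sampleBranchLengths(sampleTopology(4), 10)
#' aln <- simulateAlignment(tr, jcParams(), 50)
#' logLikelihood(tr, jcParams(), aln)
#' @export
logLikelihood <- function(tree, params, data) {
  stopifnot(inherits(tree, "phylo"), is(params, "ModelParams"))
  if (is(data, "Alignment")) data <- compressPatterns(data)
  stopifnot(is(data, "PatternTable"))
  if (length(tree$tip.label) != length(data@taxa) ||
      !setequal(tree$tip.label, data@taxa))
    stop("tree tips and alignment taxa differ")
  pat <- orderPatterns(data, tree$tip.label)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  cpp_pruning_loglik(tree$edge, tree$edge.length,
                     length(tree$tip.label), pat - 1L,
                     as.numeric(data@weights), params@pi, params@er,
                     params@shape, params@pinv, params@nCategories,
                     isJC(params) && params@pinv == 0)
}

MOVE_DEFAULT_TUNING <- c(nni = 1, spr = 1, blScale = 2, betaSimplexPi = 50,
                         dirSimplexPi = 100, betaSimplexEr = 50,
                         dirSimplexEr = 100, scaleShape = 2,
                         betaProbPinv = 50)

#' Apply a single MCMC move
#'
#' Proposes one Metropolis-Hastings move from the current state and returns
#' the proposed state together with the exact log Hastings correction.
#' Exposed mainly for testing; \code{\link{runMCMC}} drives the same move
#' kernel internally.
#'
#' @param tree current \code{phylo} (with branch lengths).
#' @param params current \code{ModelParams}.
#' @param moveName one of \code{nni}, \code{spr}, \code{blScale},
#'   \code{betaSimplexPi}, \code{dirSimplexPi}, \code{betaSimplexEr},
#'   \code{dirSimplexEr}, \code{scaleShape}, \code{betaProbPinv}.
#' @param tuning the move's tuning parameter (scale-move lambda or
#'   Beta/Dirichlet concentration).
#' @return List with \code{tree}, \code{params} and \code{logHastings}
#'   (\code{-Inf} marks a proposal outside the support, to be rejected).
#' @export
applyMove <- function(tree, params, moveName,
                      tuning = MOVE_DEFAULT_TUNING[[moveName]]) {
  moveName <- match.arg(moveName, MOVE_NAMES)
  moveId <- match(moveName, MOVE_NAMES) - 1L
  out <- cpp_propose_move(tree$edge, tree$edge.length,
                          length(tree$tip.label), params@pi, params@er,
                          params@shape, params@pinv, moveId, tuning)
  ptree <- tree
  ptree$edge <- out$edge
  ptree$edge.length <- out$bl
  pp <- params
  pp@pi <- out$pi; pp@er <- out$er
  pp@shape <- out$shape; pp@pinv <- out$pinv
  lh <- out$logHastings
  if (lh < -1e200) lh <- -Inf
  list(tree = ptree, params = pp, logHastings = lh)
}

# convert a sampled edge matrix + branch lengths back into a phylo
edgesToPhylo <- function(edge, bl, tipLabels) {
  tr <- structure(list(edge = edge, edge.length = as.numeric(bl),
                       tip.label = tipLabels,
                       Nnode = length(tipLabels) - 2L),
                  class = "phylo")
  stats::reorder(tr, "cladewise")
}

PARAM_COLS <- c(paste0("pi_", NUC), paste0("er_", ER_NAMES), "shape",
                "pinv", "treeLength")

#' Run the phylogenetic MCMC sampler
#'
#' Metropolis-Hastings sampling of tree topology, branch lengths and (for
#' GTR+Gamma+I) substitution-model parameters against the joint posterior.
#' Each iteration performs \code{round(sum(moveWeights))} single-move
#' updates, each move drawn with probability proportional to its weight;
#' move tuning parameters are auto-tuned toward an acceptance rate of 0.44
#' every \code{tuneInterval} iterations. The chain starts from a draw from
#' the prior, which guarantees a finite initial posterior density.
#'
#' @param aln the observed \code{\link{Alignment}} (may be \code{NULL} when
#'   \code{priorOnly = TRUE}).
#' @param spec the \code{\link{priorSpec}} (also fixes the model flavor).
#' @param config an \code{\link{mcmcConfig}}; built from \code{spec} when
#'   missing.
#' @param priorOnly if \code{TRUE} the likelihood is held constant so the
#'   chain samples the prior — the standard sampler-correctness check.
#' @param nChains number of independent replicate chains; their post-burn-in
#'   samples are concatenated.
#' @param init optional list with elements \code{tree} and \code{params} to
#'   start from instead of a prior draw.
#' @return A \code{PosteriorTrace}.
#' @examples
#' spec <- priorSpec(4, 10, "JC")
#' tr <- samplePhyloTree(spec)
#' aln <- simulateAlignment(tr, jcParams(), 50)
#' runMCMC(aln, spec, mcmcConfig(burninIters = 50, sampleIters = 200,
#'                               thin = 10, nTaxa = 4))
#' @export
runMCMC <- function(aln, spec, config = NULL, priorOnly = FALSE,
                    nChains = 1L, init = NULL) {
  stopifnot(is(spec, "PriorSpec"))
  if (is.null(config))
    config <- mcmcConfig(nTaxa = spec@nTaxa,
                         modelFlavor = spec@modelFlavor)
  stopifnot(is(config, "MCMCConfig"))
  if (is.null(aln)) {
    if (!priorOnly) stop("an alignment is required unless priorOnly = TRUE")
    taxaLabels <- paste0("t", seq_len(spec@nTaxa))
    pat <- matrix(1L, spec@nTaxa, 1L)
    wts <- 0
  } else {
    stopifnot(is(aln, "Alignment"))
    if (nTaxa(aln) != spec@nTaxa)
      stop("alignment has ", nTaxa(aln), " taxa but spec expects ",
           spec@nTaxa)
    taxaLabels <- taxa(aln)
    ptab <- compressPatterns(aln)
    pat <- NULL  # ordered per chain against the start tree's tip order
    wts <- as.numeric(ptab@weights)
  }
  w <- setNames(numeric(length(MOVE_NAMES)), MOVE_NAMES)
  w[names(config@moveWeights)] <- config@moveWeights
  if (spec@modelFlavor == "JC" && any(w[4:9] > 0))
    stop("substitution-parameter moves are not applicable to the JC model")

  allTrees <- list(); allParams <- list(); allLP <- list(); allIt <- list()
  proposed <- accepted <- setNames(numeric(length(MOVE_NAMES)), MOVE_NAMES)
  for (ch in seq_len(nChains)) {
    if (is.null(init)) {
      tree0 <- sampleBranchLengths(sampleTopology(spec@nTaxa, taxaLabels),
                                   spec@blRate)
      params0 <- drawModelParams(spec)
    } else {
      tree0 <- init$tree
      params0 <- init$params
    }
    if (is.null(aln)) {
      chainPat <- matrix(0L, spec@nTaxa, 1L)
    } else {
      chainPat <- orderPatterns(ptab, tree0$tip.label) - 1L
    }
    res <- cpp_mcmc_chain(tree0$edge, tree0$edge.length, spec@nTaxa,
                          params0@pi, params0@er, params0@shape,
                          params0@pinv,
                          isJC(params0) && params0@pinv == 0,
                          params0@nCategories, chainPat, wts,
                          spec@blRate, spec@piAlpha, spec@erAlpha,
                          spec@shapeRate, spec@pinvBeta[1],
                          spec@pinvBeta[2], unname(w),
                          unname(MOVE_DEFAULT_TUNING),
                          config@burninIters, config@sampleIters,
                          config@thin, config@tuneInterval,
                          config@tuneDuringSampling, priorOnly)
    ns <- length(res$logPosterior)
    trees <- vector("list", ns)
    for (i in seq_len(ns))
      trees[[i]] <- edgesToPhylo(res$edges[[i]], res$bls[[i]],
                                 tree0$tip.label)
    pm <- cbind(res$pi, res$er, res$shape, res$pinv,
                vapply(res$bls, sum, 0))
    colnames(pm) <- PARAM_COLS
    allTrees[[ch]] <- trees
    allParams[[ch]] <- pm
    allLP[[ch]] <- res$logPosterior
    allIt[[ch]] <- res$iteration
    proposed <- proposed + res$proposed
    accepted <- accepted + res$accepted
  }
  new("PosteriorTrace",
      trees = do.call(c, allTrees),
      params = do.call(rbind, allParams),
      logPosterior = do.call(c, allLP),
      iteration = as.integer(do.call(c, allIt)),
      acceptance = data.frame(move = MOVE_NAMES, proposed = proposed,
                              accepted = accepted, row.names = NULL),
      config = config)
}

#' Write / read a posterior trace
#'
#' The trace is stored as two index-aligned files: \code{<prefix>.tsv} with
#' one row per sample (scalar parameters, tree length and log posterior)
#' and \code{<prefix>.trees} with the sampled trees in Newick format.
#'
#' @param trace a \code{PosteriorTrace}.
#' @param prefix output path prefix.
#' @return \code{writeTrace} returns \code{prefix} invisibly;
#'   \code{readTrace} returns a \code{PosteriorTrace} (without acceptance
#'   tallies, which are not serialized).
#' @export
writeTrace <- function(trace, prefix) {
  stopifnot(is(trace, "PosteriorTrace"))
  df <- data.frame(iteration = trace@iteration, trace@params,
                   logPosterior = trace@logPosterior)
  write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeNewick(structure(trace@trees, class = "multiPhylo"),
              paste0(prefix, ".trees"))
  invisible(prefix)
}

#' @rdname writeTrace
#' @export
readTrace <- function(prefix) {
  df <- read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t")
  trees <- readNewick(paste0(prefix, ".trees"))
  if (inherits(trees, "phylo")) trees <- list(trees)
  new("PosteriorTrace", trees = unclass(trees),
      params = as.matrix(df[, PARAM_COLS, drop = FALSE]),
      logPosterior = df$logPosterior,
      iteration = as.integer(df$iteration),
      acceptance = data.frame(move = character(), proposed = numeric(),
                              accepted = numeric()),
      config = NULL)
}
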