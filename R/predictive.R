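# Predictive dataset generation under three parameter sources: posterior
# draws, prior draws, or a single fixed value. All three share the same
# simulation kernel; they differ only in where the (tree, params) stream
# comes from.

simulateSet <- function(source, trees, paramsList, nSites) {
  alns <- vector("list", length(trees))
  for (i in seq_along(trees))
    alns[[i]] <- simulateAlignment(trees[[i]], paramsList[[i]], nSites)
  new("PredictiveSet", source = source, alignments = alns, trees = trees,
      params = paramsList)
}

traceParamsAt <- function(trace, i) {
  p <- trace@params[i, ]
  modelParams(pi = p[paste0("pi_", NUC)],
              er = p[paste0("er_", ER_NAMES)],
              shape = p[["shape"]], pinv = p[["pinv"]],
              nCategories = if (all(abs(p[paste0("pi_", NUC)] - 0.25) <
                                    1e-12) && p[["pinv"]] == 0 &&
                                   all(abs(p[paste0("er_", ER_NAMES)] -
                                           1 / 6) < 1e-12)) 1L else 4L)
}

#' Posterior predictive datasets
#'
#' Draws S parameter values from a posterior trace (evenly spaced through
#' the thinned samples, wrapping around when S exceeds the trace length)
#' and simulates one alignment of the observed dimensions under each.
#'
#' @param trace a \code{PosteriorTrace}.
#' @param nSites number of sites of the observed data.
#' @param S number of predictive datasets (the standard analysis uses 1,001
#'   for data-based and 501 for inference-based test statistics).
#' @param iid draw trace indices i.i.d. with replacement instead of evenly
#'   spaced (a sensitivity-check mode).
#' @return A \code{PredictiveSet} with source \code{"posterior"}.
#' @export
posteriorPredictive <- function(trace, nSites, S = 1001L, iid = FALSE) {
  stopifnot(is(trace, "PosteriorTrace"))
  len <- nSamples(trace)
  if (len < 1L) stop("posterior trace is empty")
  S <- as.integer(S)
  if (S < 0L) stop("S must be nonnegative")
  idx <- if (iid) sample.int(len, S, replace = TRUE)
         else (as.integer(floor((seq_len(S) - 1) * len / S)) %% len) + 1L
  simulateSet("posterior", trace@trees[idx],
              lapply(idx, traceParamsAt, trace = trace), nSites)
}

#' Prior predictive datasets
#'
#' Parameters drawn i.i.d. from the prior; otherwise as
#' \code{\link{posteriorPredictive}}.
#'
#' @param spec a \code{\link{priorSpec}}.
#' @param nSites number of sites.
#' @param S number of datasets.
#' @return A \code{PredictiveSet} with source \code{"prior"}.
#' @export
priorPredictive <- function(spec, nSites, S) {
  stopifnot(is(spec, "PriorSpec"))
  S <- as.integer(S)
  if (S < 0L) stop("S must be nonnegative")
  trees <- replicate(S, samplePhyloTree(spec), simplify = FALSE)
  paramsList <- replicate(S, drawModelParams(spec), simplify = FALSE)
  simulateSet("prior", trees, paramsList, nSites)
}

#' Fixed-parameter predictive datasets
#'
#' All S datasets are simulated under a single supplied (tree, parameters)
#' value — the sampling distribution used by fixed-null (frequentist-style)
#' checks.
#'
#' @param tree the generating \code{phylo}.
#' @param params the generating \code{ModelParams}.
#' @param nSites number of sites.
#' @param S number of datasets.
#' @return A \code{PredictiveSet} with source \code{"fixed"}.
#' @export
fixedPredictive <- function(tree, params, nSites, S) {
  S <- as.integer(S)
  if (S < 0L) stop("S must be nonnegative")
  simulateSet("fixed", rep(list(tree), S), rep(list(params), S), nSites)
}

#' Write a predictive set to disk
#'
#' One numbered FASTA file per dataset plus a manifest TSV linking each
#' dataset to its generating parameter draw (tree length, base frequencies,
#' shape, pinv) and a Newick file of the generating trees.
#'
#' @param pset a \code{PredictiveSet}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writePredictiveSet <- function(pset, dir) {
  stopifnot(is(pset, "PredictiveSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  S <- length(pset@alignments)
  files <- sprintf("rep%04d.fasta", seq_len(S))
  for (i in seq_len(S))
    writeFasta(pset@alignments[[i]], file.path(dir, files[i]))
  writeNewick(structure(pset@trees, class = "multiPhylo"),
              file.path(dir, "generating.trees"))
  man <- data.frame(
    dataset = files,
    treeLength = vapply(pset@trees,
                        function(t) sum(t$edge.length), 0),
    t(vapply(pset@params, function(p)
      c(p@pi, p@er, p@shape, p@pinv),
      numeric(12)))
  )
  colnames(man)[3:14] <- c(paste0("pi_", NUC), paste0("er_", ER_NAMES),
                           "shape", "pinv")
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
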