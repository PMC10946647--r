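# Midpoint P-values, posterior predictive effect sizes, and aggregation of
# replicate results into expected-distribution characterizations.

#' Lower one-tailed midpoint P-value
#'
#' p = (#\{T_rep < T_obs\} + 0.5 #\{T_rep = T_obs\}) / S: half of the
#' predictive values tied with the observed value are counted as more
#' extreme, half as less. Ties are detected within a relative tolerance of
#' 1e-12, which is exact for integer-valued statistics and guards against
#' floating-point coincidence for continuous ones.
#'
#' @param observed the observed statistic value T(y).
#' @param predictive numeric vector of predictive values T(y_rep).
#' @return The midpoint P-value in [0, 1].
#' @examples
#' midpointPValue(2, c(1, 2, 2, 3))  # 0.5
#' @export
midpointPValue <- function(observed, predictive) {
  if (length(predictive) < 1L) stop("predictive vector must be nonempty")
  tol <- 1e-12 * pmax(abs(observed), abs(predictive), 1)
  ties <- abs(predictive - observed) <= tol
  below <- predictive < observed & !ties
  (sum(below) + 0.5 * sum(ties)) / length(predictive)
}

#' Posterior predictive effect size
#'
#' |T(y) - median(T(y_rep))| / sd(T(y_rep)) with the (S-1)-denominator
#' standard deviation. When the predictive distribution is degenerate
#' (sd = 0) the effect size is 0 if the observed value coincides with it
#' and \code{Inf} otherwise; infinite values are excluded (and counted) by
#' the aggregation step rather than imputed.
#'
#' @param observed the observed statistic value.
#' @param predictive numeric vector of predictive values (length >= 2).
#' @return Nonnegative effect size, possibly \code{Inf}.
#' @examples
#' effectSize(4, c(0, 1, 2, 3, 4))  # 2 / sd = 1.2649
#' @export
effectSize <- function(observed, predictive) {
  if (length(predictive) < 2L)
    stop("at least 2 predictive values required")
  s <- sd(predictive)
  num <- abs(observed - median(predictive))
  if (s == 0) {
    if (num == 0) 0 else Inf
  } else {
    num / s
  }
}

#' Summarize one statistic's predictive comparison
#'
#' Combines the observed value and its predictive distribution into the
#' lower one-tailed midpoint P-value and the effect size. A two-tailed
#' convenience column min(p, 1-p) is included but plays no role in any
#' downstream summary.
#'
#' @param name statistic name.
#' @param observed observed value (NA propagates to NA summaries).
#' @param predictive predictive values; NAs are dropped (and counted).
#' @return One-row data.frame: statistic, observed, p, pTwoTailed,
#'   effectSize, S, nUndefined.
#' @export
ppSummarize <- function(name, observed, predictive) {
  bad <- is.na(predictive)
  pred <- predictive[!bad]
  if (is.na(observed) || length(pred) < 2L) {
    return(data.frame(statistic = name, observed = observed, p = NA_real_,
                      pTwoTailed = NA_real_, effectSize = NA_real_,
                      S = length(pred), nUndefined = sum(bad) +
                        is.na(observed)))
  }
  p <- midpointPValue(observed, pred)
  data.frame(statistic = name, observed = observed, p = p,
             pTwoTailed = min(p, 1 - p),
             effectSize = effectSize(observed, pred), S = length(pred),
             nUndefined = sum(bad))
}

#' Posterior predictive summaries for a whole statistic suite
#'
#' Computes the chosen statistics on the observed alignment and on every
#' predictive dataset, then the midpoint P-value and effect size per
#' statistic. Inference-based statistics require a trace for the observed
#' data and one per predictive dataset.
#'
#' @param observed the observed \code{\link{Alignment}}.
#' @param pset a \code{PredictiveSet}.
#' @param which \code{"data_based"}, \code{"inference_based"} or
#'   \code{"both"}.
#' @param observedTrace \code{PosteriorTrace} for the observed data
#'   (inference-based statistics only).
#' @param predictiveTraces list of \code{PosteriorTrace}, one per
#'   predictive dataset (inference-based statistics only).
#' @return data.frame with one row per statistic (see
#'   \code{\link{ppSummarize}}).
#' @export
ppCheck <- function(observed, pset,
                    which = c("data_based", "inference_based", "both"),
                    observedTrace = NULL, predictiveTraces = NULL) {
  which <- match.arg(which)
  out <- list()
  if (which %in% c("data_based", "both")) {
    obsStats <- dataStatistics(observed)
    predStats <- vapply(pset@alignments, dataStatistics,
                        numeric(length(dataStatisticNames())))
    out <- c(out, lapply(dataStatisticNames(), function(nm)
      ppSummarize(nm, obsStats[[nm]], predStats[nm, ])))
  }
  if (which %in% c("inference_based", "both")) {
    if (is.null(observedTrace) || is.null(predictiveTraces))
      stop("inference-based statistics need observedTrace and ",
           "predictiveTraces")
    obsStats <- inferenceStatistics(observedTrace)
    predStats <- vapply(predictiveTraces, inferenceStatistics,
                        numeric(length(inferenceStatisticNames())))
    out <- c(out, lapply(inferenceStatisticNames(), function(nm)
      ppSummarize(nm, obsStats[[nm]], predStats[nm, ])))
  }
  do.call(rbind, out)
}

#' Characterize a replicate P-value distribution
#'
#' Histogram (20 bins on [0,1]), moments, and a one-sample
#' Kolmogorov-Smirnov comparison against Uniform(0,1) — the sampling
#' distribution frequentist P-values would have. The asymptotic KS P-value
#' is only reported for 50 or more defined replicates.
#'
#' @param pvalues replicate P-values (NAs allowed; excluded and counted).
#' @return List with \code{n}, \code{nUndefined}, \code{mean}, \code{var},
#'   \code{histogram} (20 counts), \code{breaks}, \code{ksStatistic},
#'   \code{ksPValue}.
#' @export
aggregatePValues <- function(pvalues) {
  bad <- is.na(pvalues)
  p <- sort(pvalues[!bad])
  if (length(p) < 2L) stop("at least 2 defined replicates required")
  breaks <- seq(0, 1, length.out = 21L)
  h <- tabulate(pmin(pmax(ceiling(p * 20), 1L), 20L), nbins = 20L)
  n <- length(p)
  # KS distance to Uniform(0,1) computed directly (ties among replicate
  # P-values are expected for discrete statistics and are not an error)
  dPlus <- max(seq_len(n) / n - p)
  dMinus <- max(p - (seq_len(n) - 1) / n)
  ks <- max(dPlus, dMinus)
  ksP <- if (n >= 50L)
    suppressWarnings(stats::ks.test(p, "punif")$p.value)
  else NA_real_
  list(n = n, nUndefined = sum(bad), mean = mean(p), var = var(p),
       histogram = h, breaks = breaks, ksStatistic = ks, ksPValue = ksP)
}

#' Spearman correlations between statistics' replicate P-values
#'
#' Pairwise-complete Spearman rank correlations across the replicate axis;
#' constant columns yield NA for their pairs.
#'
#' @param pmatrix replicates x statistics matrix of P-values.
#' @return Symmetric correlation matrix.
#' @export
statisticCorrelations <- function(pmatrix) {
  if (nrow(pmatrix) < 3L) stop("at least 3 replicates required")
  if (ncol(pmatrix) < 2L) stop("at least 2 statistics required")
  suppressWarnings(cor(pmatrix, method = "spearman",
                       use = "pairwise.complete.obs"))
}
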