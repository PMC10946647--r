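# The test-statistic suite: 11 data-based statistics computed on
# alignments and 9 inference-based statistics computed on posterior traces.

#' Statistic registries
#'
#' Names of the data-based (alignment-level) and inference-based
#' (posterior-trace-level) test statistics, in the order the suite
#' computes them.
#'
#' @return Character vector of statistic names.
#' @export
dataStatisticNames <- function() {
  c("n_invariant", "max_invariant_block", "max_pairwise_diff",
    "max_variable_block", "min_pairwise_diff", "mean_gc", "var_gc",
    "theta_w", "tajimas_d", "tajimas_pi", "multinomial_lnl")
}

#' @rdname dataStatisticNames
#' @export
inferenceStatisticNames <- function() {
  c("mean_rf", "rf_q25", "rf_q50", "rf_q75", "rf_q99", "rf_q999",
    "entropy", "mean_tl", "var_tl")
}

alnCodes <- function(aln) {
  m <- alignmentMatrix(aln)
  matrix(match(m, NUC), nrow = nrow(m), dimnames = dimnames(m))
}

#' Invariant-site statistics
#'
#' A column is invariant when all its characters are identical. Returns the
#' number of invariant columns and the maximum run lengths of consecutive
#' invariant and consecutive variable columns (0 when no such column
#' exists).
#'
#' @param aln an \code{\link{Alignment}}.
#' @return Named vector \code{(n_invariant, max_invariant_block,
#'   max_variable_block)}.
#' @export
invariantSiteStats <- function(aln) {
  codes <- alnCodes(aln)
  inv <- matrixStats_colAllEqual(codes)
  r <- rle(inv)
  maxRun <- function(val) {
    x <- r$lengths[r$values == val]
    if (length(x)) max(x) else 0L
  }
  c(n_invariant = sum(inv), max_invariant_block = maxRun(TRUE),
    max_variable_block = maxRun(FALSE))
}

matrixStats_colAllEqual <- function(codes) {
  if (nrow(codes) == 1L) return(rep(TRUE, ncol(codes)))
  colSums(codes != rep(codes[1L, ], each = nrow(codes))) == 0L
}

# matrix of pairwise mismatch counts via base-indicator cross products
mismatchMatrix <- function(codes) {
  L <- ncol(codes)
  matches <- matrix(0, nrow(codes), nrow(codes))
  for (b in 1:4) matches <- matches + tcrossprod(codes == b)
  L - matches
}

#' Pairwise-difference statistics
#'
#' Scaled mismatch counts (mismatches / number of sites) for the most and
#' least divergent sequence pairs.
#'
#' @param aln an \code{\link{Alignment}} with at least 2 taxa.
#' @return Named vector \code{(min_pairwise_diff, max_pairwise_diff)}.
#' @export
pairwiseDifferenceStats <- function(aln) {
  codes <- alnCodes(aln)
  if (nrow(codes) < 2L) stop("at least 2 sequences required")
  d <- mismatchMatrix(codes)[lower.tri(diag(nrow(codes)))] / ncol(codes)
  c(min_pairwise_diff = min(d), max_pairwise_diff = max(d))
}

#' GC-content statistics
#'
#' Per-sequence GC fraction, summarized by its mean and its variance
#' (denominator n - 1) across sequences.
#'
#' @param aln an \code{\link{Alignment}}.
#' @return Named vector \code{(mean_gc, var_gc)}.
#' @export
gcStats <- function(aln) {
  codes <- alnCodes(aln)
  gc <- rowMeans(codes == 2L | codes == 3L)
  c(mean_gc = mean(gc),
    var_gc = if (length(gc) > 1L) var(gc) else 0)
}

nSegregating <- function(codes) sum(!matrixStats_colAllEqual(codes))

harmonic <- function(n) sum(1 / seq_len(n))

#' Watterson's theta
#'
#' Number of segregating (variable) columns divided by the harmonic number
#' a1 = sum(1/i, i = 1..n-1). Reported per alignment, not per site.
#'
#' @param aln an \code{\link{Alignment}} with at least 2 taxa.
#' @return Watterson's theta estimate.
#' @export
wattersonTheta <- function(aln) {
  codes <- alnCodes(aln)
  n <- nrow(codes)
  if (n < 2L) stop("at least 2 sequences required")
  nSegregating(codes) / harmonic(n - 1L)
}

#' Nucleotide diversity (Tajima's pi)
#'
#' Mean raw mismatch count over all unordered sequence pairs.
#'
#' @param aln an \code{\link{Alignment}} with at least 2 taxa.
#' @return Mean pairwise difference count.
#' @export
tajimasPi <- function(aln) {
  codes <- alnCodes(aln)
  n <- nrow(codes)
  if (n < 2L) stop("at least 2 sequences required")
  mean(mismatchMatrix(codes)[lower.tri(diag(n))])
}

#' Tajima's D
#'
#' The classical standardized difference between nucleotide diversity and
#' Watterson's theta, using the 1989 constants. Undefined (NA) when there
#' are no segregating sites; callers exclude and count such replicates
#' rather than imputing a value.
#'
#' @param aln an \code{\link{Alignment}} with at least 4 taxa.
#' @return Tajima's D, or \code{NA} when no site segregates.
#' @export
tajimasD <- function(aln) {
  codes <- alnCodes(aln)
  n <- nrow(codes)
  if (n < 4L) stop("at least 4 sequences required")
  S <- nSegregating(codes)
  if (S == 0L) return(NA_real_)
  a1 <- harmonic(n - 1L)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  piHat <- mean(mismatchMatrix(codes)[lower.tri(diag(n))])
  (piHat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Unconstrained multinomial log likelihood of site patterns
#'
#' T = sum over distinct patterns of N_p * ln(N_p / N), the log likelihood
#' of the saturated multinomial over site patterns; 0 when every column is
#' the same pattern and N * ln(1/N) when all are distinct.
#'
#' @param aln an \code{\link{Alignment}}.
#' @return The multinomial log likelihood (<= 0).
#' @export
multinomialLikelihood <- function(aln) {
  pt <- compressPatterns(aln)
  N <- sum(pt@weights)
  sum(pt@weights * log(pt@weights / N))
}

#' All data-based statistics of an alignment
#'
#' @param aln an \code{\link{Alignment}}.
#' @return Named numeric vector over \code{\link{dataStatisticNames}}.
#' @export
dataStatistics <- function(aln) {
  inv <- invariantSiteStats(aln)
  pw <- pairwiseDifferenceStats(aln)
  gc <- gcStats(aln)
  out <- c(inv["n_invariant"], inv["max_invariant_block"],
           pw["max_pairwise_diff"], inv["max_variable_block"],
           pw["min_pairwise_diff"], gc,
           theta_w = wattersonTheta(aln), tajimas_d = tajimasD(aln),
           tajimas_pi = tajimasPi(aln),
           multinomial_lnl = multinomialLikelihood(aln))
  out[dataStatisticNames()]
}

# ---- tree statistics ----------------------------------------------------

# nontrivial bipartitions of an unrooted tree as canonical character keys
treeSplits <- function(tree) {
  nTip <- length(tree$tip.label)
  edge <- tree$edge
  desc <- vector("list", nTip + tree$Nnode)
  for (i in seq_len(nTip)) desc[[i]] <- i
  po <- stats::reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(po)))
    desc[[po[e, 1L]]] <- c(desc[[po[e, 1L]]], desc[[po[e, 2L]]])
  internal <- edge[edge[, 2L] > nTip, 2L]
  keys <- character(0)
  tipOrd <- order(tree$tip.label)  # label-based, robust to tip numbering
  rk <- match(seq_len(nTip), tipOrd)
  for (v in internal) {
    tips <- sort(rk[desc[[v]]])
    if (length(tips) <= 1L || length(tips) >= nTip - 1L) next
    if (1L %in% tips) tips <- setdiff(seq_len(nTip), tips)
    keys <- c(keys, paste(tips, collapse = "."))
  }
  unique(keys)
}

#' Robinson-Foulds distance
#'
#' Unnormalized symmetric-difference count of nontrivial bipartitions
#' between two unrooted topologies on the same leaf set.
#'
#' @param t1,t2 \code{phylo} trees with identical tip labels.
#' @return Nonnegative integer RF distance.
#' @export
rfDistance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same leaf set")
  s1 <- treeSplits(t1)
  s2 <- treeSplits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# ordered-vector quantile: element at index ceiling(q * m) of the sorted
# vector
orderedQuantile <- function(sorted, q) sorted[max(1L, ceiling(q * length(sorted)))]

#' RF-distance summary over a posterior sample of trees
#'
#' RF distances are computed over a deterministic pair set: all unordered
#' pairs when at most 200 trees are supplied, otherwise 20,000 random pairs
#' drawn under a fixed internal seed. Quantiles use the ordered-vector
#' convention (element \code{ceiling(q * m)} of the sorted vector).
#'
#' @param trees list of \code{phylo} trees (or a \code{PosteriorTrace}).
#' @return Named vector \code{(mean_rf, rf_q25, rf_q50, rf_q75, rf_q99,
#'   rf_q999)}.
#' @export
rfSummary <- function(trees) {
  if (is(trees, "PosteriorTrace")) trees <- sampledTrees(trees)
  m <- length(trees)
  if (m < 2L) stop("at least 2 sampled trees required")
  splits <- lapply(trees, treeSplits)
  if (m <= 200L) {
    pairs <- which(upper.tri(diag(m)), arr.ind = TRUE)
  } else {
    seedKeep <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(seedKeep))
      assign(".Random.seed", seedKeep, globalenv()))
    set.seed(m %% 1000000L + 17L)
    pairs <- cbind(sample.int(m, 20000L, replace = TRUE),
                   sample.int(m, 20000L, replace = TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  }
  d <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- splits[[pairs[i, 1]]]
    b <- splits[[pairs[i, 2]]]
    length(setdiff(a, b)) + length(setdiff(b, a))
  }, 0L)
  ds <- sort(d)
  c(mean_rf = mean(d), rf_q25 = orderedQuantile(ds, 0.25),
    rf_q50 = orderedQuantile(ds, 0.50), rf_q75 = orderedQuantile(ds, 0.75),
    rf_q99 = orderedQuantile(ds, 0.99),
    rf_q999 = orderedQuantile(ds, 0.999))
}

#' Topological information gain (entropy statistic)
#'
#' Prior Shannon entropy of the uniform distribution over the (2n-5)!!
#' unrooted topologies minus the empirical entropy of the sampled
#' topologies (natural log): ln((2n-5)!!) + sum(f * ln f). When every
#' sampled tree is unique among m samples this equals ln((2n-5)!!) - ln(m)
#' regardless of the data — the diffuse-posterior regime where the
#' statistic carries no information.
#'
#' @param trees list of \code{phylo} trees (or a \code{PosteriorTrace}).
#' @param nTaxa number of taxa (defaults to the trees' tip count).
#' @return The estimated information gain in nats.
#' @export
topologyEntropy <- function(trees, nTaxa = NULL) {
  if (is(trees, "PosteriorTrace")) trees <- sampledTrees(trees)
  if (length(trees) < 1L) stop("at least 1 sampled tree required")
  if (is.null(nTaxa)) nTaxa <- length(trees[[1]]$tip.label)
  keys <- vapply(trees, function(t)
    paste(sort(treeSplits(t)), collapse = "|"), "")
  f <- table(keys) / length(keys)
  logDoubleFactorial(2L * nTaxa - 5L) + sum(f * log(f))
}

logDoubleFactorial <- function(k) sum(log(seq(1L, k, by = 2L)))

#' Tree-length summary over a posterior sample
#'
#' @param trees list of \code{phylo} trees (or a \code{PosteriorTrace}).
#' @return Named vector \code{(mean_tl, var_tl)} (variance denominator
#'   n - 1).
#' @export
treeLengthStats <- function(trees) {
  if (is(trees, "PosteriorTrace")) trees <- sampledTrees(trees)
  if (length(trees) < 2L) stop("at least 2 sampled trees required")
  tl <- vapply(trees, function(t) sum(t$edge.length), 0)
  c(mean_tl = mean(tl), var_tl = var(tl))
}

#' All inference-based statistics of a posterior trace
#'
#' @param trace a \code{PosteriorTrace} (or plain list of trees).
#' @return Named numeric vector over \code{\link{inferenceStatisticNames}}.
#' @export
inferenceStatistics <- function(trace) {
  trees <- if (is(trace, "PosteriorTrace")) sampledTrees(trace) else trace
  c(rfSummary(trees), entropy = topologyEntropy(trees),
    treeLengthStats(trees))[inferenceStatisticNames()]
}
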