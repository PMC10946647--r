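# Substitution-model machinery: prior draws, discrete-Gamma rates and
# transition probabilities for JC and GTR+Gamma+I.

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Draw substitution-model parameters from the prior
#'
#' For the JC flavor the parameters are fixed (equal base frequencies and
#' exchangeabilities, a single rate category, no invariable sites). For
#' GTR+Gamma+I, base frequencies and exchangeabilities are drawn from their
#' Dirichlet priors, the Gamma shape from its Exponential prior and the
#' invariable-site proportion from its Beta prior.
#'
#' @param spec a \code{\link{priorSpec}}.
#' @return A \code{ModelParams}.
#' @examples
#' drawModelParams(priorSpec(16, 10, "JC"))
#' @export
drawModelParams <- function(spec) {
  stopifnot(is(spec, "PriorSpec"))
  if (spec@modelFlavor == "JC") return(jcParams())
  repeat {
    pinv <- rbeta(1, spec@pinvBeta[1], spec@pinvBeta[2])
    if (pinv < 1) break  # Beta can round to 1 in degenerate corners
  }
  modelParams(pi = rdirichlet1(spec@piAlpha), er = rdirichlet1(spec@erAlpha),
              shape = rexp(1, spec@shapeRate), pinv = pinv,
              nCategories = 4L)
}

#' Discretize a Gamma rate distribution
#'
#' Splits the Gamma(shape, rate = shape) distribution (mean 1) into
#' \code{k} equal-probability categories and returns the mean rate of each
#' inter-quantile interval, so that the category rates average exactly 1.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @return Numeric vector of k category rates with mean 1.
#' @examples
#' discretizeGamma(0.5, 4)
#' @export
discretizeGamma <- function(shape, k = 4L) {
  if (!is.finite(shape) || shape <= 0) stop("shape must be positive")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1)
  # mean of X ~ Gamma(a, rate a) over each quantile interval:
  # E[X; X <= q] = pgamma(q, a + 1, rate = a) since the mean is 1
  q <- qgamma(seq_len(k - 1) / k, shape = shape, rate = shape)
  cum <- c(0, pgamma(q, shape = shape + 1, rate = shape), 1)
  k * diff(cum)
}

# Unnormalized GTR rate matrix from pi and er; rows/cols in order A,C,G,T.
gtrRateMatrix <- function(pi, er) {
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (p in seq_len(6)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    Q[i, j] <- er[p] * pi[j]
    Q[j, i] <- er[p] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Rate matrix normalized so the mean substitution rate at stationarity is 1.
normalizedRateMatrix <- function(params) {
  Q <- gtrRateMatrix(params@pi, params@er)
  mu <- -sum(params@pi * diag(Q))
  Q / mu
}

#' Transition probability matrix
#'
#' Row-stochastic matrix of substitution probabilities over an edge of
#' length \code{t} (in expected substitutions per site at stationarity)
#' scaled by a site-rate multiplier. The rate matrix is normalized so the
#' mean rate at stationarity equals 1. JC uses the closed form; GTR goes
#' through a symmetric eigendecomposition of the reversible rate matrix.
#'
#' @param params a \code{ModelParams}.
#' @param t branch length (>= 0).
#' @param rate site-rate multiplier (> 0); a rate of 0 yields the identity.
#' @return 4x4 row-stochastic matrix in nucleotide order A, C, G, T.
#' @examples
#' transitionMatrix(jcParams(), 0.1)
#' @export
transitionMatrix <- function(params, t, rate = 1) {
  stopifnot(is(params, "ModelParams"))
  if (!is.finite(t) || t < 0) stop("branch length t must be nonnegative")
  if (rate < 0) stop("rate must be nonnegative")
  d <- rate * t
  if (isJC(params)) {
    e <- exp(-4 * d / 3)
    P <- matrix(0.25 - 0.25 * e, 4, 4, dimnames = list(NUC, NUC))
    diag(P) <- 0.25 + 0.75 * e
    return(P)
  }
  Q <- normalizedRateMatrix(params)
  pi <- params@pi
  # symmetrize: S = D^{1/2} Q D^{-1/2} is symmetric for reversible Q
  sq <- sqrt(pi)
  S <- (sq %o% (1 / sq)) * Q
  S <- (S + t(S)) / 2  # clean numerical asymmetry
  eg <- eigen(S, symmetric = TRUE)
  P <- ((1 / sq) %o% sq) *
    (eg$vectors %*% (exp(eg$values * d) * t(eg$vectors)))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(NUC, NUC)
  P
}

isJC <- function(params) {
  all(abs(params@pi - 0.25) < 1e-12) && all(abs(params@er - 1 / 6) < 1e-12)
}

# Site-rate mixture implied by ModelParams: rates and class probabilities.
# Invariable sites form a rate-0 class with probability pinv; the k Gamma
# categories share the remaining mass equally. JC (1 category) has rate 1.
siteRateMixture <- function(params) {
  if (params@nCategories == 1L && params@pinv == 0)
    return(list(rates = 1, probs = 1))
  rates <- discretizeGamma(params@shape, params@nCategories)
  k <- params@nCategories
  if (params@pinv > 0)
    list(rates = c(0, rates), probs = c(params@pinv,
                                        rep((1 - params@pinv) / k, k)))
  else
    list(rates = rates, probs = rep(1 / k, k))
}

# Log prior density of ModelParams under a PriorSpec (GTR_GI flavor);
# constant (0) for JC where nothing is free.
logPriorParams <- function(params, spec) {
  if (spec@modelFlavor == "JC") return(0)
  ldirichlet <- function(x, a)
    sum((a - 1) * log(x)) + lgamma(sum(a)) - sum(lgamma(a))
  ldirichlet(params@pi, spec@piAlpha) +
    ldirichlet(params@er, spec@erAlpha) +
    dexp(params@shape, spec@shapeRate, log = TRUE) +
    dbeta(params@pinv, spec@pinvBeta[1], spec@pinvBeta[2], log = TRUE)
}
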