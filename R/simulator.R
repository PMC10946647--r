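# Synthetic-data module: trees and alignments drawn from the generative
# model, plus the standard simulation settings.

#' Sample a tree topology uniformly
#'
#' Draws an unrooted labeled binary topology uniformly over the
#' (2n-5)!! possibilities by sequential random edge addition: starting from
#' the 3-taxon star, each further taxon is attached to an edge chosen
#' uniformly at random. The returned \code{phylo} is represented with a
#' trifurcation at its root node, the standard encoding of an unrooted
#' binary tree.
#'
#' @param nTaxa number of taxa (>= 4).
#' @param labels taxon labels; defaults to t1..tn.
#' @return An ape \code{phylo} without branch lengths.
#' @examples
#' sampleTopology(16)
#' @export
sampleTopology <- function(nTaxa, labels = paste0("t", seq_len(nTaxa))) {
  nTaxa <- as.integer(nTaxa)
  if (nTaxa < 4L) stop("nTaxa must be >= 4")
  root <- nTaxa + 1L
  nEdge <- 2L * nTaxa - 3L
  parent <- integer(nEdge); child <- integer(nEdge)
  parent[1:3] <- root; child[1:3] <- 1:3
  m <- 3L                       # current number of edges
  for (k in 4:nTaxa) {
    r <- sample.int(m, 1L)
    w <- nTaxa + k - 2L         # new internal node id
    # split edge r: (a,b) -> (a,w), (w,b); attach leaf k below w
    b <- child[r]
    child[r] <- w
    parent[m + 1L] <- w; child[m + 1L] <- b
    parent[m + 2L] <- w; child[m + 2L] <- k
    m <- m + 2L
  }
  tr <- structure(list(edge = cbind(parent, child, deparse.level = 0),
                       tip.label = labels, Nnode = nTaxa - 2L),
                  class = "phylo")
  stats::reorder(tr, "cladewise")
}

#' Draw branch lengths from the Exponential prior
#'
#' @param topology a \code{phylo}.
#' @param blRate Exponential rate; lengths have mean \code{1/blRate}.
#' @return The tree with i.i.d. Exponential branch lengths attached.
#' @export
sampleBranchLengths <- function(topology, blRate) {
  stopifnot(inherits(topology, "phylo"), blRate > 0)
  topology$edge.length <- rexp(nrow(topology$edge), rate = blRate)
  topology
}

#' Draw a complete tree (topology + branch lengths) from the prior
#'
#' @param spec a \code{\link{priorSpec}}.
#' @return An ape \code{phylo} with branch lengths.
#' @export
samplePhyloTree <- function(spec) {
  stopifnot(is(spec, "PriorSpec"))
  sampleBranchLengths(sampleTopology(spec@nTaxa), spec@blRate)
}

# Transition-matrix factory: precomputes the eigendecomposition once per
# parameter value so per-edge P matrices are cheap.
tmFactory <- function(params) {
  if (isJC(params)) {
    return(function(t, rate) {
      e <- exp(-4 * rate * t / 3)
      P <- matrix(0.25 - 0.25 * e, 4, 4)
      diag(P) <- 0.25 + 0.75 * e
      P
    })
  }
  Q <- normalizedRateMatrix(params)
  sq <- sqrt(params@pi)
  S <- (sq %o% (1 / sq)) * Q
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  left <- (1 / sq) * eg$vectors           # rows scaled
  right <- t(sq * eg$vectors)             # columns scaled, transposed
  function(t, rate) {
    P <- left %*% (exp(eg$values * rate * t) * right)
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

#' Simulate a DNA alignment along a tree
#'
#' Sites are i.i.d.: each site draws a rate class (invariable with
#' probability pinv, otherwise one of the discrete Gamma categories), a
#' root state from the equilibrium frequencies, and then evolves down the
#' tree via the transition probabilities of each edge. The root is placed
#' at the tree's (trifurcating) root node; by time-reversibility the
#' resulting distribution over alignments does not depend on that choice.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param params a \code{ModelParams}.
#' @param nSites number of sites (>= 1).
#' @return An \code{\link{Alignment}}.
#' @examples
#' tr <- sampleBranchLengths(sampleTopology(5), 10)
#' simulateAlignment(tr, jcParams(), 20)
#' @export
simulateAlignment <- function(tree, params, nSites) {
  stopifnot(inherits(tree, "phylo"), is(params, "ModelParams"))
  nSites <- as.integer(nSites)
  if (nSites < 1L) stop("nSites must be >= 1")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  mix <- siteRateMixture(params)
  siteCat <- sample.int(length(mix$rates), nSites, replace = TRUE,
                        prob = mix$probs)
  catIdx <- split(seq_len(nSites), siteCat)
  tm <- tmFactory(params)
  states <- matrix(0L, nNode, nSites)
  root <- nTip + 1L
  states[root, ] <- sample.int(4L, nSites, replace = TRUE,
                               prob = params@pi)
  edge <- tree$edge; bl <- tree$edge.length
  for (e in seq_len(nrow(edge))) {
    a <- edge[e, 1L]; b <- edge[e, 2L]
    for (cc in names(catIdx)) {
      idx <- catIdx[[cc]]
      r <- mix$rates[as.integer(cc)]
      ps <- states[a, idx]
      if (r == 0 || bl[e] == 0) {
        states[b, idx] <- ps
      } else {
        cp <- tm(bl[e], r)
        cp <- cp %*% upper.tri(diag(4), diag = TRUE)  # row cumsums
        u <- runif(length(idx))
        states[b, idx] <- 1L + as.integer((cp[ps, 1L] < u) +
                                          (cp[ps, 2L] < u) +
                                          (cp[ps, 3L] < u))
      }
    }
  }
  out <- states[seq_len(nTip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  Alignment(out)
}

#' Standard simulation settings
#'
#' The five canonical conditions: a JC baseline with 16 taxa, 100 sites and
#' mean branch length 0.1, then one-at-a-time modifications (64 taxa; 1,000
#' sites; mean branch length 0.02; GTR+Gamma+I).
#'
#' @param setting integer 1..5.
#' @return A list with elements \code{spec} (a \code{PriorSpec}) and
#'   \code{nSites}.
#' @examples
#' simulationSetting(1)
#' @export
simulationSetting <- function(setting) {
  setting <- as.integer(setting)
  if (!setting %in% 1:5) stop("setting must be in 1..5")
  tab <- list(
    list(flavor = "JC",     nTaxa = 16L, nSites = 100L,  blRate = 10),
    list(flavor = "JC",     nTaxa = 64L, nSites = 100L,  blRate = 10),
    list(flavor = "JC",     nTaxa = 16L, nSites = 1000L, blRate = 10),
    list(flavor = "JC",     nTaxa = 16L, nSites = 100L,  blRate = 50),
    list(flavor = "GTR_GI", nTaxa = 16L, nSites = 100L,  blRate = 10)
  )[[setting]]
  list(spec = priorSpec(tab$nTaxa, tab$blRate, tab$flavor),
       nSites = tab$nSites)
}
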