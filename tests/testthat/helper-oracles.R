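# Independent oracles and fixture builders. Every oracle here is a second,
# deliberately naive implementation (enumeration, quadrature, closed form)
# kept independent of the package's computational path.

NUC4 <- c("A", "C", "G", "T")

# brute-force pruning oracle: sums the site likelihood over all internal
# node state assignments and rate classes; feasible for <= 6 taxa
oracleBruteLogLik <- function(tree, params, aln) {
  tree <- stats::reorder(tree, "cladewise")
  m <- alignmentMatrix(aln)
  codes <- matrix(match(m, NUC4), nrow = nrow(m),
                  dimnames = dimnames(m))
  codes <- codes[tree$tip.label, , drop = FALSE]
  mix <- phyloppc:::siteRateMixture(params)
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  edge <- tree$edge
  bl <- tree$edge.length
  ints <- (nTip + 1):nNode
  grid <- as.matrix(expand.grid(rep(list(1:4), length(ints))))
  ll <- 0
  for (s in seq_len(ncol(codes))) {
    sl <- 0
    for (ci in seq_along(mix$rates)) {
      r <- mix$rates[ci]
      Ps <- lapply(seq_len(nrow(edge)), function(e)
        if (r == 0) diag(4) else transitionMatrix(params, bl[e], r))
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nNode)
        st[seq_len(nTip)] <- codes[, s]
        st[ints] <- grid[g, ]
        pr <- params@pi[st[nTip + 1]]
        for (e in seq_len(nrow(edge)))
          pr <- pr * Ps[[e]][st[edge[e, 1]], st[edge[e, 2]]]
        tot <- tot + pr
      }
      sl <- sl + mix$probs[ci] * tot
    }
    ll <- ll + log(sl)
  }
  ll
}

# analytic site-pattern probabilities for a 3-taxon JC star tree with
# terminal branch lengths b1, b2, b3, rooted at the internal node
oraclePatternProbs3 <- function(b) {
  P <- lapply(b, function(d) {
    e <- exp(-4 * d / 3)
    M <- matrix(0.25 - 0.25 * e, 4, 4)
    diag(M) <- 0.25 + 0.75 * e
    M
  })
  probs <- array(0, c(4, 4, 4))
  for (x1 in 1:4) for (x2 in 1:4) for (x3 in 1:4) {
    p <- 0
    for (s in 1:4)
      p <- p + 0.25 * P[[1]][s, x1] * P[[2]][s, x2] * P[[3]][s, x3]
    probs[x1, x2, x3] <- p
  }
  probs
}

# independently coded Tajima's D from the published constant definitions,
# with pairwise differences counted by explicit double loop
oracleTajimasD <- function(aln) {
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  tot <- 0
  np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ])
    np <- np + 1
  }
  piHat <- tot / np
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piHat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# brute-force midpoint P-value by direct counting
oracleMidpointP <- function(obs, pred) {
  (sum(pred < obs) + 0.5 * sum(pred == obs)) / length(pred)
}

# canonical topology key via the package's split computation
topologyKey <- function(tree)
  paste(sort(phyloppc:::treeSplits(tree)), collapse = "|")

# alignment built from explicit sequence strings
alnFromStrings <- function(...) {
  ss <- c(...)
  m <- do.call(rbind, strsplit(ss, ""))
  rownames(m) <- paste0("t", seq_along(ss))
  Alignment(m)
}

# a fixed 2-taxon "tree": single internal node joining both tips
twoTaxonTree <- function(d) {
  structure(list(edge = cbind(c(3L, 3L), c(1L, 2L)),
                 edge.length = c(d / 2, d / 2),
                 tip.label = c("t1", "t2"), Nnode = 1L),
            class = "phylo")
}

# fixed 3-taxon star tree
threeTaxonTree <- function(b) {
  structure(list(edge = cbind(c(4L, 4L, 4L), c(1L, 2L, 3L)),
                 edge.length = b,
                 tip.label = c("t1", "t2", "t3"), Nnode = 1L),
            class = "phylo")
}
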