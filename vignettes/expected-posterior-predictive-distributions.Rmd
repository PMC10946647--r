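---
title: "Expected distributions of posterior predictive P-values in phylogenetics"
author: "phyloppc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected distributions of posterior predictive P-values in phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloppc)
```

## The question the package answers

Posterior prediction is the standard Bayesian machinery for checking the
absolute fit of a phylogenetic model: fit the model to an alignment $y$,
draw $S$ parameter values $\theta_1,\dots,\theta_S$ from the posterior
$p(\theta \mid y)$, simulate one replicate alignment $y^{rep}_s$ under each
draw, and compare a test statistic $T(y)$ against the predictive
distribution of $T(y^{rep})$. The tail area

$$
p \;=\; \int_{-\infty}^{T(y)}
\left( \int p(T(y^{rep}) \mid \theta)\, p(\theta \mid y)\, d\theta \right)
dT(y^{rep})
$$

is the posterior predictive P-value. Unlike a frequentist hypothesis-test
P-value — whose defining property is uniformity under the null — this
quantity conditions on parameters that were *fitted to the same data*, so
even when the analysis model exactly matches the generating process its
replicate distribution is generally nonuniform and concentrated near 0.5.
`phyloppc` implements, as a tested and seed-reproducible pipeline, a
simulation study that characterizes those expected distributions: the
generative model, the MCMC sampler, predictive dataset generation, a
20-statistic test suite, and the distribution summaries.

Three parameter sources for the predictive stream are supported, differing
only in where $\theta$ comes from while sharing one simulation kernel:
posterior draws (`posteriorPredictive()`), prior draws
(`priorPredictive()`, the Bayesian analog of a fixed-null test), and a
single fixed value (`fixedPredictive()`). The parametric-bootstrap variant
(predictive simulation under a maximum-likelihood estimate) is out of
scope: the package deliberately contains no ML optimizer.

## Generative model and priors

Data are simulated under either Jukes–Cantor (JC) or GTR+$\Gamma$+I on
unrooted binary trees. The joint prior, which is also the prior used for
inference, is:

| parameter | prior | default hyperparameters |
|---|---|---|
| topology $\Psi$ | uniform over unrooted labeled binary topologies | — |
| branch lengths | i.i.d. Exponential($\lambda_{bl}$) | $\lambda_{bl} = 10$ or $50$ |
| base frequencies $\pi$ | Dirichlet($\alpha_\pi$) | $(1,1,1,1)$ |
| exchangeabilities $er$ | Dirichlet($\alpha_{er}$) | $(1,1,1,1,1,1)$ |
| $\Gamma$ shape $\alpha$ | Exponential($\lambda_\alpha$) | $0.05$ (mean 20) |
| invariable proportion $I$ | Beta($\alpha_I, \beta_I$) | $(10, 20)$ (mean 1/3) |

The five canonical study conditions are one JC baseline (16 taxa, 100
sites, mean branch length 0.1) and four one-at-a-time modifications: 64
taxa, 1,000 sites, mean branch length 0.02, and GTR+$\Gamma$+I
(`simulationSetting(1:5)`). Branch lengths are in expected substitutions
per site.

Numerical conventions, fixed once:

* Nucleotide order is A, C, G, T; exchangeability order AC, AG, AT, CG,
  CT, GT.
* The GTR rate matrix is normalized to unit mean substitution rate at
  stationarity; transition probabilities go through the symmetric
  eigendecomposition of $D_\pi^{1/2} Q D_\pi^{-1/2}$ (JC uses its closed
  form).
* Among-site rate variation uses four equal-probability discrete
  $\Gamma$ categories whose rates are the *mean* of each inter-quantile
  interval, so the category rates average exactly 1 (`discretizeGamma()`).
* The invariable-site class is a fifth, zero-rate mixture component with
  weight $I$; rate-matrix normalization excludes it, i.e. branch lengths
  count expected substitutions per *variable-process* site. This is a
  declared convention; an alternative normalization would rescale branch
  lengths by $1 - I$ without changing the logic anywhere else.
* Uniform topology draws use sequential random edge addition (attach
  taxon $k{+}1$ to one of the $2k-3$ edges uniformly), which is exactly
  uniform over the $(2n-5)!!$ unrooted shapes.
* Simulation roots the unrooted tree at its trifurcating representation
  node; by time-reversibility (the pulley principle) the sampling
  distribution of alignments does not depend on that choice, and a test
  pins the two-rooting equivalence of the analytic pattern probabilities.

## The sampler

`runMCMC()` is a Metropolis–Hastings sampler over $(\Psi, bl)$ and, for
GTR+$\Gamma$+I, $(\pi, er, \alpha, I)$, with the likelihood computed by
Felsenstein pruning over compressed site patterns in C++. The move set and
weights mirror standard practice: NNI (weight $= n_{taxa}$), SPR (weight
$= 0.1\, n_{taxa}$), single-branch scaling (weight $= n_{taxa}$), and for
the richer model Beta/Dirichlet simplex moves on $\pi$ and $er$ (weights
2, 1, 3, 1.5), a scale move on $\alpha$ (2) and a Beta move on $I$ (2). JC
analyses use only the first three moves.

Choices the study design leaves open, resolved as follows:

* **Iteration semantics.** One iteration performs
  $\mathrm{round}(\sum w)$ single-move updates, each move drawn with
  probability proportional to its weight. A random-scan schedule preserves
  the stationary distribution unambiguously.
* **Proposals and Hastings factors.** Branch/shape scaling multiplies by
  $e^{\lambda(u - 1/2)}$ with log-Hastings $\log(\text{multiplier})$. SPR
  prunes a uniformly chosen subtree whose parent is not the
  representation root, merges the two flanking edges, regrafts at a
  uniform point on a uniformly chosen eligible edge, and corrects by
  $\log L_{target} - \log(l_1 + l_2)$. The Beta-simplex move redraws one
  simplex element from $\mathrm{Beta}(a x_i + 1,\, a(1-x_i) + 1)$ and
  rescales the rest (with the $(K{-}2)$-dimensional rescaling Jacobian in
  the Hastings factor); the Dirichlet-simplex move proposes from
  $\mathrm{Dirichlet}(a x + 1)$.
* **Auto-tuning.** Every 200 iterations each tunable move's boldness is
  multiplied by $\exp(\mathrm{clip}(\hat a - 0.44, \pm 0.5))$, where
  $\hat a$ is the window acceptance rate (applied inversely to
  concentration-style tuning parameters). Data-style analyses tune during
  burn-in and sampling; inference-style predictive re-analyses tune during
  burn-in only.
* **Initialization and thinning.** Chains start from a fresh prior draw
  (guaranteed support); the default thinning keeps about 200 states.
  Two independent replicate chains with concatenated post-burn-in samples
  are available via `nChains`.

Because every proposal is validated against the exact posterior ratio,
the sampler's correctness surface is prior recovery: with the likelihood
held constant (`priorOnly = TRUE`), every free parameter's marginal must
match its prior (Kolmogorov–Smirnov) and 4-taxon topologies must be
uniform ($\chi^2$) — both are asserted in the test suite. There is no
partial-likelihood caching: at the study's alignment sizes a full C++
recomputation per proposal is fast enough, and it keeps the sampler free
of cache-invalidation state.

## Test statistics and summaries

Eleven data-based statistics are computed directly on alignments: number
of invariant sites, maximum invariant and variable block lengths, minimum
and maximum scaled pairwise differences, mean and variance of per-sequence
GC content, Watterson's $\theta$, Tajima's D, nucleotide diversity
($\bar\pi$), and the unconstrained multinomial log likelihood of site
patterns. Nine inference-based statistics summarize a posterior trace:
mean Robinson–Foulds distance and its 0.25/0.5/0.75/0.99/0.999
ordered-vector quantiles, topological information gain (entropy), and the
mean and variance of tree length. Conventions the tables of statistics do
not pin down, fixed here:

* "Scaled" pairwise differences are mismatches divided by alignment
  length — the only scale-free choice. Watterson's $\theta$ and
  $\bar\pi$ are reported per alignment, not per site; since midpoint
  P-values are invariant to any monotone rescaling applied to observed
  and predictive values alike, this cannot change any P-value.
* Tajima's D is undefined when no site segregates; such replicates are
  excluded and counted, never imputed.
* RF summaries use all unordered tree pairs when the trace holds at most
  200 trees, otherwise 20,000 internally-seeded random pairs; quantiles
  take element $\lceil q\,m \rceil$ of the sorted distance vector.
* Entropy is prior minus posterior Shannon entropy in nats,
  $\ln((2n-5)!!) + \sum_t \hat f_t \ln \hat f_t$. When every sampled tree
  is unique among $m$ samples this is $\ln((2n-5)!!) - \ln m$ for any
  data — the diffuse-posterior regime in which the statistic is constant
  across replicates.

Each statistic is reduced to the **lower one-tailed midpoint P-value**
$p = (\#\{T^{rep} < T(y)\} + \tfrac12 \#\{T^{rep} = T(y)\})/S$ — ties,
ubiquitous for discrete statistics, are split evenly — and the **effect
size** $|T(y) - \mathrm{median}(T^{rep})| / \mathrm{sd}(T^{rep})$.
Ties are detected within a relative tolerance of $10^{-12}$ (exact for
integer statistics; for continuous ones, independent simulations tie only
through floating-point coincidence). A degenerate predictive distribution
(zero sd) yields effect size 0 or a flagged infinity that aggregation
excludes and counts. Replicate P-value distributions are characterized by
20-bin histograms, moments, and a KS comparison against Uniform(0,1)
(asymptotic P-value reported only for $n \ge 50$); cross-statistic
dependence uses pairwise-complete Spearman correlations.

## What the generator does and does not emulate

The simulator produces exactly the regime the expected-distribution
question is about: i.i.d. sites, no indels or ambiguity codes,
stationarity and homogeneity along the tree, and an analysis model
identical to the generating model with matching priors. Passing tests
therefore certify the *calibration* of the machinery under a correctly
specified model — they say nothing about power to detect misspecification
on real data, where alignment columns are not independent, compositions
drift, and no model is exactly true. Two further caveats: GC-content
statistics are only *approximately* ancillary under JC — their
distributions are invariant to the equilibrium frequencies, but extreme
tree-depth contrasts change between-sequence correlation and hence the
spread of per-sequence GC, which is visible in a two-sample test across a
very shallow versus a very deep fixed tree; and effect-size distributions
are scale-dependent even for ancillary statistics.

## Problem sizes

The production-scale design (10,000 replicates with 1,001 predictive
datasets for data-based statistics; 1,000 replicates with 501 for
inference-based ones; 10,000-iteration chains) is a cluster-sized
computation. The package runs the identical design at configurable scale;
its reference desk-scale run — used by the acceptance checks and
reproduced by `scripts/acceptance.R` — is 100 replicates of the baseline
setting with 1,200-iteration chains thinned to 100 draws and 100
posterior predictive datasets per replicate, which completes in a couple
of minutes on one core. Per-predictive-dataset chains for inference-based
statistics default to a shortened burn-in 100 / 500 iterations — a
declared scale parameter, not a silent change. Replicates are seeded
deterministically from the master seed, so runs are reproducible and
resumable replicate by replicate (`runExperiment()` refuses to resume
over a mismatched configuration hash).

```{r, eval = FALSE}
cfg <- experimentConfig(
  setting = 1, nDatasets = 100, sPredictive = 100,
  statistics = "data_based",
  mcmc = mcmcConfig(burninIters = 200, sampleIters = 1000, thin = 10,
                    nTaxa = 16),
  seed = 1)
res <- runExperiment(cfg)
res$pvalueSummaries$n_invariant$var   # << 1/12: concentration near 0.5
res$pvalueSummaries$var_gc$ksPValue   # > 0.01: ancillary, ~uniform
```

## Known limitations

* No maximum-likelihood machinery, hence no parametric-bootstrap
  P-values.
* Convergence is by design: the matched-model regime with prior draws as
  starting states and spot-checkable acceptance tallies; no formal
  convergence diagnostics are computed.
* The SPR proposal never prunes a subtree hanging directly from the
  representation root; those rearrangements remain reachable through
  other prune choices and NNI, so the chain is irreducible, but mixing on
  pathological trees could differ from a fully uniform SPR.
* Codon/amino-acid models, non-reversible models, among-branch rate
  heterogeneity, partitioned simulation and gap handling are out of
  scope.
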