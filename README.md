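# phyloppc

Posterior predictive checks are the standard Bayesian tool for asking
whether a phylogenetic substitution model can reproduce the salient
features of the alignment it was fitted to. Their output is a tail-area
"P-value", but it is **not** a frequentist P-value: because the model's
parameters were fitted to the very data being checked, the replicate
distribution of posterior predictive P-values is nonuniform even when the
analysis model exactly matches the generating process — typically
concentrated around 0.5, uniform only for (approximately) ancillary
statistics, and multimodal for discrete ones. Misreading these values on
the frequentist scale systematically *understates* evidence of poor fit.

`phyloppc` is a tested, seed-reproducible pipeline for characterizing
those expected distributions, aimed at researchers who use or develop
model-adequacy methods in phylogenetics. It provides:

* a generative model and simulator for JC and GTR+Γ+I on unrooted trees,
  with parameters drawn from their priors (topology uniform; branch
  lengths Exponential(λ_bl); π ~ Dirichlet(1,1,1,1);
  er ~ Dirichlet(1,…,1); Γ shape ~ Exponential(0.05); invariable
  proportion ~ Beta(10,20)), covering the five standard study settings
  (16/64 taxa, 100/1,000 sites, mean branch length 0.1/0.02, JC vs
  GTR+Γ+I);
* a Metropolis–Hastings MCMC sampler over topology, branch lengths and
  substitution-model parameters (NNI, SPR, scaling and simplex moves with
  weight-proportional scheduling and acceptance-targeted auto-tuning),
  with a Felsenstein-pruning likelihood over compressed site patterns in
  C++;
* predictive dataset generation from three parameter sources — posterior
  draws, prior draws, or a fixed value — sharing one simulation kernel;
* the full 20-statistic suite: 11 data-based statistics (invariant-site
  counts and blocks, scaled pairwise differences, GC mean/variance,
  Watterson's θ, Tajima's D, nucleotide diversity, multinomial pattern
  likelihood) and 9 inference-based statistics (Robinson–Foulds mean and
  ordered-vector quantiles, topological entropy, tree-length moments);
* lower one-tailed **midpoint P-values**,
  `p = (#{T_rep < T_obs} + ½ #{T_rep = T_obs}) / S`, and **effect sizes**
  `|T(y) − median(T_rep)| / sd(T_rep)`, aggregated into histogram /
  moment / KS-versus-uniform summaries and cross-statistic Spearman
  correlations;
* config-driven experiment orchestration with per-replicate seeding and
  resumability, plus FASTA/NEXUS/Newick I/O and a thin command-line
  wrapper (`inst/cli/ppd.R`).

The methods vignette
(`vignettes/expected-posterior-predictive-distributions.Rmd`) documents
the model, the sampler's proposal and tuning rules, every convention the
statistic definitions leave open, and what desk-scale runs do and do not
demonstrate.

## Worked example

One complete check of a single matched-model dataset — simulate from the
prior, fit by MCMC, generate 100 posterior predictive datasets, and
summarize all 11 data-based statistics:

```r
library(phyloppc)
set.seed(7)

spec   <- priorSpec(16, blRate = 10, modelFlavor = "JC")
tree   <- samplePhyloTree(spec)
params <- drawModelParams(spec)
aln    <- simulateAlignment(tree, params, 100)

trace <- runMCMC(aln, spec,
                 mcmcConfig(burninIters = 200, sampleIters = 1000,
                            thin = 10, nTaxa = 16))
pset  <- posteriorPredictive(trace, nSites = 100, S = 100)
res   <- ppCheck(aln, pset)
res[, c("statistic", "observed", "p", "effectSize")]
```

```
             statistic  observed     p effectSize
1          n_invariant  1.00e+00 0.015      2.246
2  max_invariant_block  1.00e+00 0.385      0.000
3    max_pairwise_diff  6.20e-01 0.165      0.747
4   max_variable_block  7.70e+01 0.990      2.878
5    min_pairwise_diff  5.00e-02 0.355      0.355
6              mean_gc  4.64e-01 0.125      1.168
7               var_gc  9.73e-04 0.320      0.379
8              theta_w  2.98e+01 0.985      2.246
9            tajimas_d  1.68e+00 0.150      1.007
10          tajimas_pi  4.15e+01 0.460      0.174
11     multinomial_lnl -4.58e+02 0.225      0.575
```

Each row compares the observed statistic with its posterior predictive
distribution: `p` is the lower midpoint P-value (here e.g. only 1.5% of
predictive datasets had fewer-or-tied invariant sites than the observed
one — an unremarkable value for a single replicate, since under a matched
model these P-values scatter widely around 0.5), and `effectSize` is the
discrepancy in predictive standard deviations. Characterizing the
*distribution* of these quantities over many replicate datasets is what
`runExperiment()` does:

```r
cfg <- experimentConfig(setting = 1, nDatasets = 100, sPredictive = 100,
                        statistics = "data_based",
                        mcmc = mcmcConfig(burninIters = 200,
                                          sampleIters = 1000, thin = 10,
                                          nTaxa = 16),
                        seed = 1)
res <- runExperiment(cfg)
res$pvalueSummaries$n_invariant$var  # 0.0699 < 1/12: concentration
res$pvalueSummaries$var_gc$ksPValue  # 0.18: ancillary statistic, ~uniform
quantile(res$effectSizes, 0.95)      # 1.76: effect sizes nearly always < 2
```

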