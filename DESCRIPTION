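Package: phyloppc
Title: Posterior Predictive Checks for Bayesian Phylogenetic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, inference and summary machinery for characterizing
    the expected behavior of posterior predictive model checks in Bayesian
    phylogenetics. Provides a substitution-model simulator (JC and
    GTR+Gamma+I) drawing trees and parameters from their priors, a
    Metropolis-Hastings MCMC sampler over topologies, branch lengths and
    substitution-model parameters using Felsenstein pruning with site-pattern
    compression, posterior/prior/fixed-parameter predictive dataset
    generation, a suite of data-based and inference-based test statistics,
    lower one-tailed midpoint P-values and posterior predictive effect
    sizes, and config-driven experiment orchestration across the standard
    simulation settings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
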