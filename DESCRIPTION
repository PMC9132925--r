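Package: seedburial
Title: Seed-Burial Experiments: Persistence Classification, Phylogenetic
    Logistic Models and Viability Equations
Version: 0.1.0
Authors@R: person("Seedbank", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-year seed-burial experiments on soil
    seed banks. Computes per-bag seed viability, germinability and
    germination from exhumation counts, classifies species seed banks as
    transient, short-term or long-term persistent, builds phylogenetic
    correlation matrices from Newick trees (with genus-level grafting of
    missing taxa), fits Bayesian phylogenetic binomial-logistic mixed
    models by MCMC (fixed effects, variance components, Pagel's lambda,
    posterior-predictive decline curves over 0-10 years), estimates
    Ellis-Roberts viability-equation parameters and P50 per species, and
    generates fully synthetic burial experiments with known ground truth
    for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
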