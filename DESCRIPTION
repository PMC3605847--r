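Package: riverNe
Title: Local and Metapopulation Effective Size from Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates contemporary local effective population size (Ne) from
    single-sample microsatellite genotypes using linkage disequilibrium with
    low-frequency-allele screening and an approximate Bayesian computation
    estimator, detects first-generation immigrants by genotype-likelihood
    ratios with a Monte Carlo null, and computes metapopulation effective size
    (meta-Ne) under seven models of spatial genetic structure, including a
    dominant-eigenvalue analysis of the drift-migration coancestry recursion
    for arbitrary asymmetric migration matrices. A forward-time Wright-Fisher
    riverscape simulator generates Genepop-format synthetic data emulating
    linearly connected pond systems with waterfall barriers and provides
    realized-Ne oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
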