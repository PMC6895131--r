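Package: fireocc
Title: Bayesian Occupancy Models for Wildfire Severity and Pyrodiversity
    Effects on Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Single-season hierarchical occupancy models for acoustic
    detection/non-detection surveys across burn-severity gradients. Provides
    a synthetic-data generator for spatially autocorrelated severity
    landscapes and multi-night survey designs, multi-scale buffer covariates
    with a residual-regression pyrodiversity index, a marginalized Bernoulli
    occupancy likelihood with adaptive Metropolis MCMC (Rcpp), PSIS-LOO
    comparison of candidate spatial scales, and posterior-propagated
    community diversity (summed-occupancy richness and detection-corrected
    Jaccard beta diversity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
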