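Package: gsbench
Title: Genomic Selection Benchmarking on a Simulated Growth-Curve Trait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a factorial-mating population in which a cumulative
    yield trait follows a logistic growth curve controlled by 18 QTL, and
    benchmarks genomic prediction methods on it: pedigree BLUP, GBLUP and
    ridge-regression BLUP, and Bayesian whole-genome regressions (BayesA,
    BayesB, BayesC and the Bayesian Lasso) fitted by Gibbs sampling.
    Includes the prediction strategies needed to move phenotypes or
    estimated breeding values to an extrapolated time point (growth-curve
    fitting, linear and quadratic extrapolation), a best-case analysis that
    regresses fitted curve parameters on true QTL genotypes, and the
    evaluation statistics (accuracy, bias slope, top-decile rank
    correlation, centered mean squared prediction error) used to compare
    methods against true breeding values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
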