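Package: thrlmm
Title: Multi-Trait Threshold-Linear Mixed Models for Genetic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint genetic prediction of multiple ordinal categorical and
    continuous traits under Wright's liability threshold model coupled with a
    linear mixed model. Location parameters (fixed effects and breeding
    values) are estimated as joint posterior modes (MAP) by Newton-Raphson
    or by a SQUAREM-accelerated Expectation-Maximization scheme, both built
    on truncated multivariate normal moments and sparse mixed model
    equations; a single-site Gibbs sampler with known variance components
    provides a posterior-mean benchmark. Includes pedigree relationship
    machinery (Henderson's A-inverse, single-step H-inverse), a synthetic
    data simulator for overlapping-generation pedigrees with correlated
    categorical and continuous traits, and agreement analytics between
    solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    mvtnorm,
    truncnorm,
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
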