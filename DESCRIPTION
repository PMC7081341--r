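Package: modscreen
Title: Multi-Modular, Abstention-Capable Screening Classifiers for
    Ordinal Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating multi-modular diagnostic
    screeners from ordinal questionnaire score sheets: an
    abstention-capable ("inconclusive") classifier cascade built on
    gradient-boosted decision trees, setting-noise estimation from paired
    clinic/deployment answers and its stochastic injection into training
    data, distribution-shift feature rejection, perturbation-based
    question ranking, inverse-covariance combination of module responses
    with leave-one-out covariance estimation and dual-threshold
    inconclusive banding, and bootstrap comparison of screeners (delta
    AUC and delta specificity at fixed sensitivity). A synthetic
    ordinal-item generator with a latent-trait graded-response model,
    deployment-setting severity drift and analyst skips makes the whole
    pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
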