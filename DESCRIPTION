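Package: scrdens
Title: Bayesian Spatial Capture-Recapture Density Estimation with Model
    Selection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates animal density from trap-array capture histories
    using Bayesian spatial capture-recapture (SCR) models fitted by
    data-augmentation Markov chain Monte Carlo. Supports sex-specific
    baseline detection and movement-scale covariates, a tunable
    exponential-to-Gaussian detection kernel, collapsing of capture
    histories across sampling-interval lengths (daily, weekly, monthly,
    quarterly), Bayesian model selection via the Gelfand-Dey
    approximation to marginal likelihoods with Bayes factors and
    posterior model probabilities, and a simulator for power analysis
    and end-to-end testing of camera-trap study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
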