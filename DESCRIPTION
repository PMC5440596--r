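Package: grtkit
Title: General Recognition Theory Analyses for 2x2 Identification and
    Garner Filtering Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing perceptual separability, perceptual
    independence and decisional separability with General Recognition
    Theory (GRT), the multidimensional extension of signal detection
    theory. Implements summary-statistics analyses (macro and micro) of
    4x4 confusion matrices from 2x2 identification experiments,
    maximum-likelihood fitting and AICc selection over the 12-model
    traditional GRT hierarchy, the GRT-wIND multi-participant model with
    likelihood-ratio tests, summary-statistics analysis of the 2x2
    Garner filtering task (Garner interference, marginal response
    invariance, marginal response-time invariance), model plots, and
    simulators for all three data types.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
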