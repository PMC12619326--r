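Package: serialdep
Title: Serial Dependence in Orientation Estimation: Models, Bias Analysis,
    and Simulation-Based Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying serial dependence in orientation-adjustment
    tasks. Implements circular arithmetic and wrapped-normal densities on the
    180-degree orientation space, a Bayesian ideal observer with a
    natural-statistics transition prior, a two-component demixing model of
    current and previous stimuli fit by multi-restart expectation-maximization,
    a seeded generator of synthetic adjustment-task experiments with a planted
    derivative-of-Gaussian serial bias, the behavioral bias-analysis pipeline
    (cardinal-bias removal, outlier exclusion, kernel-weighted density-asymmetry
    curves, per-degree condition tests with cluster reporting, peak
    localization), and simulation-based power analysis for repeated-measures
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
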