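Package: socialMarkov
Title: Markov Modelling and Metrics for Social Preference Behavior
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing and simulating two-stimulus social
    preference tests in rodents. Implements a four-state discrete-time
    Markov simulator of social investigation whose transition
    probabilities evolve with stimulus reward and environmental anxiety,
    strain presets for mouse and rat social-preference and
    social-novelty-preference tests, the standard behavioral metrics
    pipeline for investigation event logs (gap-merged bouts, binned
    investigation time, bout-duration categories, relative differential
    investigation, stimulus transitions, center/periphery occupancy,
    dyadic contact metrics), a piezoelectric movement-detection pipeline
    (band-pass filtering, threshold crossing, movement-triggered
    investigation), evolutionary multiobjective fitting of model
    parameters to cohort summary curves, and seeded synthetic-data
    generators with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
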