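Package: streakvision
Title: Early-Vision Modelling of Intra-Saccadic Motion Streaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the visual consequences of rapid target motion during
    saccadic eye movements. Provides a synthetic trial generator (bandpass
    noise targets, saccade and target trajectories, retinotopic input
    movies), a physiologically scaled log-Gabor filter bank, temporal
    response functions derived from a spatiotemporal contrast-sensitivity
    surface, quadrature energy computation with delayed divisive
    normalization, model-output summaries over spatial-frequency and
    orientation channels, and a predictive switch model that converts
    intra-saccadic response dynamics into prediction-error (gaze-correction
    trigger) times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
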