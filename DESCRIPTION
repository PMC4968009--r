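Package: movelsp
Title: Fast Lomb-Scargle Periodograms and Periodicity Tests for Animal
    Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Spectral analysis of irregularly sampled animal telemetry.
    Implements an exact, FFT-based Lomb-Scargle periodogram for location
    time series with missing fixes, variable sampling intervals, multiple
    spatial dimensions and multiple individuals; an O(N^2) least-squares
    reference implementation; exact Gaussian simulators for the standard
    aperiodic continuous-time movement models (Brownian motion,
    Ornstein-Uhlenbeck position, integrated Ornstein-Uhlenbeck, and the
    position-velocity OUF model); maximum-likelihood fitting and
    AICc selection of these models; a Monte-Carlo null-model test of
    periodicity that is valid under temporally autocorrelated background
    noise and inherits the data's sampling schedule; and diagnostics for
    artefactual periodicities created by the sampling schedule itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite
Config/testthat/edition: 3
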