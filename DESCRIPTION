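Package: vnspupil
Title: Parametric Vagus Nerve Stimulation Analysis with Pupillometry,
    Cholinergic Imaging and Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for parametric vagus nerve stimulation (VNS)
    experiments in head-fixed mice: pupil and eyelid signal conditioning
    (blink detection, interpolation, zero-phase low-pass filtering,
    percentile normalization), evoked-response epoching and scalar
    quantification, pseudo-trial correction for reversion to the mean,
    multivariate log-logistic dose-response surface fitting over pulse
    amplitude, width and rate (and its charge-per-pulse reduction),
    log-spaced charge-bin statistics with false-discovery-rate control,
    cross-validated nerve-engagement prediction with bootstrap mediation
    path analysis, cluster-based permutation testing of pixelwise calcium
    response maps, phase-locked eye-movement power, and stimulation
    electronics characterization (current leak fraction and pulse-width
    filtering).  Includes a synthetic-session generator that emulates the
    statistical structure of the recordings so that every stage is testable
    without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
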