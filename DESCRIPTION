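Package: trackephys
Title: Single-Neuron Encoding, Decoding and Gamma-Band Analyses for
    Linear-Track Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for extracellular recordings made while
    rodents run a two-platform linear-track reward-seeking task. Provides a
    synthetic-session generator with known ground truth; behavioral
    preprocessing (two-pass Kalman smoothing of tracking, trial segmentation,
    position linearization, 50-ms binning); waveform-based unit classification
    and optotagging tests; cross-validated Poisson encoding models with
    circular-shift permutation inference on unique explained variance;
    direction-resolved spatial statistics (modulation index, spatial
    information, spatial consistency); linear-SVM decoding of traversal
    direction; LFP spectral analysis including gamma-burst detection and
    optogenetic resonance; and spike-gamma phase-coupling statistics
    (pairwise phase consistency, mean resultant length, Rayleigh test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    pracma,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
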