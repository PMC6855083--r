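Package: ecgsqc
Title: Cascaded Convolutional Networks for Dynamic ECG Signal Quality
    Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies 4-second single-lead Holter (dynamic) ECG segments
    into five interference classes (low interference, mild/severe motion
    artifact, mild/severe myoelectric noise) and three clinical quality
    levels using a two-stage cascade of convolutional neural networks: a
    first stage distinguishes interference type from a short-time Fourier
    spectrogram together with the raw waveform, and a second stage grades
    the interference level.  Includes a physiologically motivated synthetic
    generator for labelled noisy ECG segments, rule-based quality labelling
    anchored to the R-wave height, Butterworth band-pass preprocessing and
    WFDB record ingestion, a compact CPU convolutional-network engine, and
    sensitivity/specificity/accuracy evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
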