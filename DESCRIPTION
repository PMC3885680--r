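Package: fingerbci
Title: Pairwise Decoding of Individual Finger Movements from EEG Spectral
    Principal Components
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for decoding individual finger movements of one
    hand from multichannel scalp EEG. Provides kinematic movement-peak
    detection from bipolar finger sensors or data-glove traces, zero-phase
    filtering and common-average re-referencing, Hanning-windowed power
    spectral density estimation, per-channel principal component analysis of
    log-normalized spectra (decoupling a broadband movement-related component
    from alpha/beta rhythm desynchronization), r-squared based channel
    selection, pairwise classification with a radial-basis-kernel maximum
    margin classifier under repeated stratified cross-validation, and
    permutation/binomial significance assessment. Includes a synthetic-data
    generator that emulates the assumed statistical structure (1/f background,
    movement-locked broadband power increase, alpha/beta event-related
    desynchronization, ~1 Hz kinematic flexion peaks) with ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
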