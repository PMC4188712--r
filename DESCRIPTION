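Package: emgmap
Title: Spatial Mapping of Muscle Activity from High-Density Surface EMG Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multi-channel (grid) surface electromyograms recorded
    during cyclic wrist and finger movements. Provides a synthetic generator of
    grid sEMG and joint-angle data with planted spatial sources; signal
    conditioning (zero-phase Butterworth band-pass, spectral-interpolation
    power-line removal, bad-channel detection, envelope extraction); movement
    cycle segmentation from joint kinematics with range-of-motion outlier
    rejection, time normalization and waveform repeatability (coefficient of
    multiple correlation); non-negative matrix factorization of envelope maps
    into motor modules with variance-accounted-for model selection; watershed
    segmentation of spatial coefficient maps into activity clusters with
    centre-of-gravity, overlap and displacement statistics; and joint-angle
    reconstruction from envelope subsets with multilayer perceptrons under
    cycle-wise cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
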