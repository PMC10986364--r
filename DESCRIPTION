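Package: p3dseize
Title: Seizure Prediction from Multichannel EEG with Nonlinear Features
    and a Pseudo-3D Convolutional Recurrent Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for preictal/interictal classification of
    multichannel scalp EEG. Recordings are band-pass filtered, cut into
    non-overlapping 6-second windows labelled against a 15-to-5-minute
    seizure-prediction horizon, and summarised per channel by four nonlinear
    complexity measures (Higuchi fractal dimension, approximate entropy,
    sample entropy, fuzzy entropy). Features are ranked by
    minimum-redundancy-maximum-relevance (mRMR) mutual-information selection,
    mapped onto a 4x7 electrode grid, standardised, and assembled into
    two-step spatio-temporal tensors. Classification uses a pseudo-3D
    convolutional network (spatial kxkx1 and cross-feature 1x1xb factorised
    kernels), a bidirectional 3D convolutional LSTM, and squeeze-excitation
    channel attention, trained by backpropagation implemented in the package.
    Includes a deterministic synthetic-EEG generator with a controllable
    interictal/preictal complexity contrast, repeated stratified k-fold
    cross-validation with confusion-matrix metrics, KNN/SVM baselines, and
    minimal EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    e1071,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
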