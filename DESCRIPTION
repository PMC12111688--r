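Package: emoKAN
Title: Sparse-Channel EEG Emotion Recognition with a CNN-KAN Network and
    Frequency-Channel Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Emotion recognition from four frontal EEG channels (FP1, FP2,
    AF3, AF4). Extracts band-limited differential entropy, Welch band power
    and inter-hemispheric asymmetry features (EVI/ASI) from 1-second windows,
    corrects individual differences against a 3-second baseline segment,
    arranges the 48 features into 4x4x3 pseudo-RGB images, and classifies
    them with a compact convolutional network whose head is a
    Kolmogorov-Arnold (B-spline) layer and whose channel attention uses a
    Fourier descriptor (F2CA). Includes a synthetic 4-channel EEG generator
    with 1/f background and class-specific band asymmetries, adapters for
    the DEAP and SEED MATLAB releases, 10-fold cross-validation with
    support-weighted metrics, and a single-precision BLAS-backed training
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
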