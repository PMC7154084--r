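Package: megdecode
Title: Wavelet-Based Decoding of Spoken and Imagined Phrases from MEG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for decoding phrase identity from multichannel
    neuromagnetic (MEG) recordings. Provides a synthetic MEG generator with
    class-specific band-limited spatio-spectral signatures and 1/f background
    noise; epoching, zero-phase Butterworth low-pass filtering, amplitude-based
    trial rejection and channel exclusion; an undecimated Daubechies-4 wavelet
    multiresolution analysis that denoises trials and decomposes them into six
    neural oscillation bands (delta through high-gamma); RMS feature extraction
    with ANOVA/Tukey feature screening; Morlet continuous-wavelet scalograms,
    per-sensor scalogram rasters, spatial tiling of all sensors into a single
    composite image, and time-shift data augmentation; a shallow sigmoid
    artificial neural network and a small convolutional neural network decoder
    trained with the corresponding stochastic-gradient and Adam protocols; and
    a full evaluation layer with stratified splits, confusion matrices,
    one-vs-rest ROC/AUC, exact binomial chance levels and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    generics,
    ggplot2,
    signal,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    nnet
Config/testthat/edition: 3
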