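Package: forceMI
Title: Force-Level Motor-Imagery EEG Decoding with Multi-Scale Temporal
    Convolution and Channel Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying graded-force motor imagery in multichannel
    EEG. Provides a session-structured synthetic generator of event-related
    desynchronization (ERD) in the alpha and beta bands over contralateral
    sensorimotor cortex, a standard preprocessing chain (mastoid
    re-referencing, broadband and notch filtering, common average reference,
    8-30 Hz FIR filtering, resampling to 128 Hz, epoching and per-trial
    z-normalization), event-related spectral perturbation (ERSP) analysis via
    the short-time Fourier transform, and a three-class convolutional decoder
    built from a multi-scale temporal convolution module, a spatial
    convolution module, and a channel-attention recalibration stage, trained
    with mini-batch Adam under stratified k-fold cross-validation. The
    network forward and backward passes are implemented directly on
    BLAS-backed matrix operations, so no external deep-learning framework is
    required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
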