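Package: ctesm
Title: Convolutional Transformer Enhanced Sequential Models for EEG-Based
    Parkinson's Disease Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying resting-state
    electroencephalography (EEG) recordings of Parkinson's disease patients
    versus healthy controls. Provides a synthetic multichannel EEG cohort
    generator with controllable band-power class effects, readers and writers
    for EDF, BrainVision and delimited formats, overlapping-frame windowing,
    a biologically informed per-frame per-channel feature extractor (Welch
    band powers, beta/alpha ratio, median frequency, spectral entropy,
    wavelet level means, approximate entropy, skewness, kurtosis and
    zero-crossing rate), feature-level data augmentation, a hybrid
    convolutional / multi-head-attention / LSTM classifier trained with Adam
    on categorical cross-entropy, channel-wise statistical screening, and
    classification metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
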