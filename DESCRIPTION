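Package: eegdenoise
Title: EEG Artifact Removal with a 1D Full-Scale Multi-Residual Encoder-Decoder Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Removes ocular (EOG) and myogenic (EMG) artifacts from single-channel
    electroencephalogram (EEG) segments with a one-dimensional encoder-decoder
    network that combines multi-residual convolution blocks with full-scale
    residual-path skip connections. Provides SNR-controlled semi-synthetic
    contamination of clean EEG with artifact segments, a seedable surrogate
    generator for band-limited EEG/EOG/EMG segment banks, a complete training
    pipeline (Adam, mean-squared-error loss, k-fold cross-validation, optional
    deep supervision), and the standard temporal and spectral evaluation suite:
    correlation coefficients, percentage artifact reduction in time and
    frequency domains, relative root-mean-square errors, and canonical
    five-band (delta/theta/alpha/beta/gamma) power ratios from periodogram
    power spectral densities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
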