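Package: eegarrange
Title: Input Arrangements of Resting-State EEG for CNN-Based Biometric
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Compares six ways of arranging multichannel resting-state
    electroencephalography (EEG) segments as input to a fixed shallow
    convolutional neural network for closed-set subject identification:
    raw amplitude matrices, Hilbert-transform instantaneous-energy
    matrices, Pearson-correlation channel-reordered matrices, and the
    0-255 min-max image encodings of each. Includes a seeded synthetic
    cohort generator emulating eyes-open/eyes-closed baseline recordings
    (64 channels, 160 Hz) with subject-specific spectral fingerprints,
    a from-scratch CNN (two convolution + average-pooling stages, optional
    batch normalization, SGD with momentum), a threefold cross-validation
    harness, and readers/writers for the on-disk artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
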