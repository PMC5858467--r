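Package: adimpact
Title: Advertisement Impact Assessment from Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end pipeline for predicting a viewer's purchase intent
    from single-electrode EEG recorded while watching video advertisements.
    Provides a synthetic cohort generator with a latent emotion variable
    coupling band powers to questionnaire answers, FFT band-power feature
    extraction in the ThinkGear 13-column schema, threshold binarization of
    mixed ranked/binary questionnaire items, ratio-preserving ten-fold
    construction, scaled Gaussian bootstrap and combinatorial column-
    replacement augmentation, a linear maximum-margin classifier with
    squared hinge loss fitted by primal optimization, and an evaluation
    layer with in-sample runs, leave-one-subject-out averaging, threshold
    grid scans and cross-validated learning curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
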