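Package: morsecg
Title: Morse Wavelet Time-Frequency Representation and Rhythm
    Classification of ECG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for classifying single-channel electrocardiogram (ECG)
    recordings into rhythm classes (cardiac arrhythmia, congestive heart
    failure, normal sinus rhythm) via time-frequency images.  Implements the
    generalized Morse wavelet family in closed form, an analytic
    constant-Q continuous wavelet transform filterbank, jet-colormap
    scalogram image rendering, a seeded reference convolutional network
    with a pluggable backbone contract, stratified segment splitting, a
    synthetic three-class ECG generator for fully offline testing, and
    one-vs-rest multi-class evaluation metrics (sensitivity, specificity,
    precision, recall, F-measure, overall accuracy, macro averages).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
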