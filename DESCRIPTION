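Package: sonoyeast
Title: Noninvasive Ultrasonic Monitoring of Yeast Cell Count with Compact Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates pulse-echo ultrasound A-scans of Saccharomyces
    suspensions in wort, extracts nine echo-derived features (per-echo
    envelope maximum, its time, and summed rectified amplitude) after
    zero-phase bandpass filtering and block averaging, and trains compact
    fully connected neural networks (two hidden layers, L-BFGS, early
    stopping) to predict yeast cell count by regression and to classify
    strain identity by softmax. Includes group-aware train/test splitting
    with fivefold cross-validation and the standard regression and
    classification evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    arrow,
    testthat (>= 3.0.0),
    zoo
Config/testthat/edition: 3
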