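Package: vsabci
Title: Simulation and Gaze-Independent Decoding of Visual Oddball BCI Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gaze-independent operation of six-target
    hexagonal visual oddball brain-computer interfaces (BCIs). Provides a
    synthetic session generator emulating overt, covert and free
    visuospatial-attention conditions (condition-dependent P300 amplitude
    and latency jitter, gaze-dependent early visual components, colored
    background noise, binocular gaze traces with dropout), an EEG
    preprocessing chain (band-pass filtering, RANSAC bad-channel detection,
    mastoid re-referencing, epoching), three event-related potential
    decoders (block-Toeplitz LDA, xDAWN-covariance tangent-space LDA, and
    classifier-based latency estimation with Woody iterations), and
    evaluation machinery: block-wise cross-validation, cross-condition
    calibration transfer, bootstrap confidence intervals on selection
    accuracy, and repetitions-to-threshold summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
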