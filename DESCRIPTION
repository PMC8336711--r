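Package: drexr
Title: Multifeature Bayesian Sequential Prediction and Change Detection
    for Stochastic Tone Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying statistical change detection in stochastic
    melodies that vary along several perceptual features at once. Generates
    random-fractal (1/f^beta) seed sequences and maps them to pitch, spatial
    location and spectral-centroid tracks; runs a sequential Bayesian
    predictor (dynamic regularity extraction, D-REX) that maintains multiple
    context hypotheses over possible change times and emits per-tone
    surprisal and belief-change signals; enumerates 32 multifeature model
    variants crossing per-feature statistics order, early versus late
    integration, and four combination operators (AVG, wAVG, MIN, MAX);
    simulates and fits listeners by grid search with detection-rate MSE and
    a hinge loss, with cross-validation and d-prime summaries; and aligns
    multichannel epochs to model outputs (surprisal percentiles, maximal
    belief change) with equal-occupancy binning and baseline-relative rms
    magnitudes.
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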