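Package: laryx
Title: Simulation, Signal Processing and Sequential Feature Classification for Wearable Laryngeal Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for neck-worn mechano-acoustic monitoring of laryngeal
    function: a seeded simulator of triaxial acceleration plus surface-EMG
    recordings (cardiac micro-vibrations, respiration, swallowing, drinking,
    coughing, speech surrogates, locomotion and motion artifacts); spectral
    characterization (Welch power spectral density, short-time Fourier
    transform, band signal-to-noise ratio) and decoupled heart-rate and
    respiration-rate estimation; windowing of labeled recordings into
    fixed-length channel-by-time sequences; a 2D-like sequential feature
    extractor (convolutional blocks trained with joint triplet and
    cross-entropy objectives, a cosine learning-rate schedule and an
    Adam-style update with an attenuation-rate diagnostic) with
    subject-adaptation of its fully connected head; evaluation protocols
    (confusion matrices, subject holdout, t-SNE diagnostics); and an
    eight-level swallowing/drinking/talking rehabilitation scorer with
    clinical swallow-timing rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    pracma,
    Rtsne,
    cluster,
    jsonlite,
    yaml,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
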