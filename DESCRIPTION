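Package: radarvitals
Title: Heart and Respiratory Rate Estimation from Ultra-Wideband Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates heart rate and respiratory rate simultaneously from
    ultra-wideband (UWB) radar baseband recordings. Implements movement-based
    epoch exclusion, band-limited short-time Fourier spectrogram images, a
    dual-branch transfer-learning convolutional regressor, and
    Bland-Altman/correlation agreement evaluation under pooled 10-fold
    cross-validation. Ships a physically motivated synthetic chest-motion
    radar simulator (periodic breathing, cardiac motion, clutter events) so
    the full pipeline is testable without clinical recordings.
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
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    EBImage,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
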