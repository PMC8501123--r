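Package: circaptc
Title: Phase Transition Curve Reconstruction from Single-Cell Circadian Reporter Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs high-resolution circadian phase transition curves
    (PTCs) from time-lapse fluorescence traces of non-synchronized single-cell
    reporter populations given a single one-time intervention. Provides
    running-mean z-score detrending, windowed cosine fitting with an
    exhaustive period scan, tau-independent phase analysis (TIPA) for
    period-aware old/new phase extraction, two-harmonic Fourier resetting
    models for type-1 and type-0 topologies with bootstrap hypothesis tests
    (response significance, model selection by RMSE, group differences),
    dose-panel summaries, circular statistics, a synthetic oscillator
    population simulator with known ground truth, and a simplified imaging
    front end (nuclei segmentation, background subtraction, centroid
    tracking) validated on synthetic movies.
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
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
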