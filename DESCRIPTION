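Package: ripplesync
Title: Detection and Cross-Regional Coordination Analysis of Sharp-Wave Ripples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting sharp-wave ripples (SWRs) in local field
    potential recordings from hippocampal CA1 and medial entorhinal cortex
    (MEC), and for quantifying their coordination across the two regions.
    Implements ripple-band (150-250 Hz) Hilbert-envelope z-score detection
    gated by immobility, per-event metrics (duration, amplitude, power
    spectral density, frequency peak, sharp-wave co-occurrence), SWR density,
    duration-normalized cross-correlograms with peak-lag extraction,
    bivariate Granger causality on event-sparsified envelope series with
    AIC/BIC order selection and false-discovery-rate correction, group-level
    nonparametric statistics, and a seeded synthetic dual-site LFP generator
    with ground-truth event catalogs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
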