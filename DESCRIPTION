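Package: synscreen
Title: Bliss Synergy Analysis for 2D and 3D Drug-Combination Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput pairwise drug-combination
    screens run in 384-well plates on planar (2D) and spheroid (3D) cancer
    cell cultures. Normalizes raw well signals to per-plate vehicle controls,
    fits four-parameter logistic single-agent dose-response curves with
    range-censored IC20 and log-dose AUC summaries, scores 5x5 dose matrices
    against the Bliss independence reference model, classifies combinations
    as synergistic and as synergistically effective (Bliss excess below zero
    and viability at or below one half of vehicle), and quantifies
    cross-readout agreement and screen reproducibility (Pearson correlations,
    coefficients of variation). Includes a synthetic screen generator with
    known ground-truth Hill curves and injected Bliss deviations so every
    pipeline stage can be validated without raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    minpack.lm,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
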