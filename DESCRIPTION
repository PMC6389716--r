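Package: dfcvar
Title: Temporal Variability of Dynamic Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the temporal variability of dynamic
    functional connectivity (dFC) computed from region-of-interest fMRI
    time series. Segments each subject's BOLD series into non-overlapping
    windows, estimates per-window Pearson correlation networks, and
    quantifies how much each node's connectivity profile - and each
    within- and between-module connectivity block - reconfigures across
    windows. Provides permutation-based group inference, paired sign-flip
    tests, Spearman clinical correlation with outlier screening, a
    window-length robustness sweep, and a seeded synthetic-cohort
    generator with state-switching modular covariance structure so the
    whole pipeline can be exercised and validated without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
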