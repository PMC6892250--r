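Package: thicknorm
Title: Normative Modeling of Cortical Thickness in Human Visual Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and using normative models of regional
    cortical thickness on surface meshes, organised around the 25
    retinotopic visual areas of the human cortex. Provides a synthetic
    cohort generator with twin-structured rosters and latent-factor
    between-subject covariance, maximum-probability-map labeling of
    probabilistic surface atlases, per-area thickness aggregation,
    Gaussian normative fits with binned goodness-of-fit and
    Anderson-Darling normality screening under FDR control, inter-areal
    correlation clustering, hemispheric asymmetry statistics (two-way
    absolute-agreement intraclass correlation and per-area bias tests),
    leave-p-out reliability of regional means, and a seeded end-to-end
    pipeline with tabular report outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    nortest,
    car,
    ape,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
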