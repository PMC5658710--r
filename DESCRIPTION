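Package: superpca
Title: Supervised Principal Component Analysis for Clinical Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Associates high-dimensional gene-expression data with clinical
    outcomes of three types (time-to-event, continuous, binary) via supervised
    principal components: per-gene univariate screening statistics, a
    cross-validated screening threshold, train/test prediction of the leading
    principal component, and statistical association summaries with
    Kaplan-Meier, scatter, box, bar and forest plots. Includes a seeded
    synthetic-data generator with known latent signal structure for testing
    and calibration.
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
    optparse,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
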