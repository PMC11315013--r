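Package: bedtherm
Title: Unobtrusive Distal Skin Temperature Estimation from Smart-Bed Sensor Strips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the distal skin temperature (DST) of a sleeper at
    minute-level resolution from a five-sensor temperature strip embedded
    under a mattress surface. Implements minute aggregation with
    quality gating, top-three sensor selection, a sequentially trained
    two-stage regression model (gradient boosted trees followed by a
    random forest over a five-minute rolling window), subject-blocked
    cross-validation with Bland-Altman and R-squared agreement statistics,
    learning curves, and lights-off change-curve verification. Includes a
    synthetic multi-subject sleep-thermodata simulator with sensor
    quantization, contact variability and artifact injection so the whole
    pipeline can be exercised without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
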