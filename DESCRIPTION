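Package: actichange
Title: Age-Related Change in Accelerometer-Measured Activity in Youth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for longitudinal analysis of hip-worn accelerometer
    data in children and adolescents. Reads epoch-level ActiGraph-style count
    files, reintegrates them to 60-second epochs, detects non-wear bouts and
    applies an overnight exclusion window, classifies epochs into sedentary,
    light, and moderate-to-vigorous intensity by counts-per-minute cut-points,
    builds valid-day and valid-file summaries, standardizes intensity minutes
    for between-wave wear-time differences, harmonises cohort covariates, and
    estimates annual change in each behaviour with three-level (time point
    within participant within study) mixed-effects linear models, including
    stratified and effect-modification variants. A seeded synthetic-cohort
    generator produces wave-level analysis tables and epoch-level count traces
    with known ground truth, so every stage is testable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
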