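Package: skinqspr
Title: QSPR Models for Human Skin Permeability from Stratified
    Permeation Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and applies quantitative structure-permeability
    relationship (QSPR) models for the human skin permeability
    coefficient (Kp). Reads HuskinDB-style permeability and molecular
    descriptor tables, stratifies measurements by experimental scenario
    (skin source, skin layer, donor concentration class, donor
    temperature bin), fits per-scenario ordinary least-squares models of
    log10 Kp on logP, TPSA and molecular volume, selects and validates
    models with train/test splits, constructs a pooled outlier-filtered
    model, ships the published scenario equations (including a
    Potts-Guy-style baseline) as ready-to-use predictors, and generates
    synthetic datasets with known ground truth so the whole pipeline is
    testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
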