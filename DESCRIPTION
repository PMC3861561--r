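Package: ki67score
Title: Semi-Automated Ki-67 Proliferation Index Scoring and Breast
    Carcinoma Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for marker-based Ki-67 proliferation index (IK)
    scoring over calibrated microscope fields: reading, validating and
    writing per-field point annotations (CSV or GeoJSON) with micrometer
    calibration, per-field and case-level IK with the 1,000-nuclei
    minimum rule and mean-of-fields aggregation, field-count planning,
    and the breast-carcinoma stratification layer (ER/PR receptor
    levels, HER2 0-3+ scoring, luminal typing, St. Gallen IK classes,
    node score and Nottingham Prognostic Index). Includes a seeded
    synthetic field and cohort generator with known ground truth, cohort
    cross-tabulation reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
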