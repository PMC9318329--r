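Package: aabalance
Title: Amino Acid Mass Balance, Dialysis Kinetics, and Fatigue Associations in Hemodialysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-patient mass-balance quantification of amino acid losses in
    chronic hemodialysis (spent dialysate plus residual urinary excretion),
    dialysis adequacy (single-pool Daugirdas Kt/V) and protein-intake kinetics
    (Maroni formula), distribution-aware cohort comparison tables, and adjusted
    logistic-regression models of severe fatigue with sensitivity-exclusion
    suites. Includes a seeded synthetic-cohort generator that emulates the
    statistical structure of a hemodialysis cohort and matched controls, so the
    whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
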