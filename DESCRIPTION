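Package: filab
Title: Laboratory-Based Frailty Index Construction and Mortality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a deficit-accumulation frailty index from routine blood
    laboratory variables (FI-LAB): codes each of 22 lab values as a deficit
    against sex-specific reference ranges, computes the per-subject index
    with a completeness rule, classifies frailty at a configurable
    cut-point, and analyses its association with mortality through Cox
    proportional-hazards models, per-variable hazard screens, Nelson-Aalen
    cumulative-hazard curves, and Table-style group comparisons (t-tests,
    chi-square, proportion confidence intervals). Includes a calibrated
    synthetic-cohort generator (correlated Beta-Bernoulli deficits,
    proportional-hazards survival with administrative censoring) so the
    whole pipeline can be exercised and validated without access to any
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
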