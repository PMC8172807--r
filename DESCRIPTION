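Package: schoolmh
Title: Scoring and Permutation Inference for Repeated School Mental-Health Surveys
Version: 1.0.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing anonymous cross-sectional school mental-health
    surveys repeated over several years, as collected after the 2016 Fort
    McMurray wildfire. Provides declarative scoring for eight self-report
    instruments (CPSS, PHQ-A, HADS anxiety subscale, CRAFFT, tobacco use,
    Rosenberg self-esteem, Kidscreen-10, CYRM-12) including skip logic and
    reverse-coded items; consistency-based data exclusion; screening cut-off
    classification into probable diagnoses; permutation tests on linear-model
    slopes with nuisance covariates; Benjamini-Hochberg false-discovery-rate
    control across a 75-test battery; and a calibrated synthetic cohort
    generator so the entire pipeline can be exercised without access to the
    restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
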