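Package: icbstrat
Title: Clinical-Genomic Risk Stratification for Immunotherapy-Treated Head and Neck Cancer
Version: 0.1.0
Authors@R:
    person("ICB", "Stratification Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for stratifying immune-checkpoint-blockade treated head and
    neck squamous cell carcinoma cohorts from whole-exome and clinical data:
    per-patient feature derivation (tumor mutational burden, clonal load,
    systemic inflammatory response index, PD-L1 combined positive score,
    arm-level copy-number events, multi-assay HPV status), survival-guided
    dichotomization and hierarchical molecular subtyping, a portable
    four-feature rule classifier with cross-cohort TMB quantile calibration,
    a balanced-split random-survival-forest protocol with repeated
    permutation-importance pruning, a three-feature recursive-partitioning
    risk classifier, contingency and rank statistics, and a synthetic-cohort
    generator that reproduces the statistical structure of a two-etiology
    immunotherapy cohort for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
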