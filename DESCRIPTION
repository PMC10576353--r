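Package: epimr
Title: Summary-Statistic Mendelian Randomization and Matched
    Case-Control Inference for Circulating Biomarkers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Inference chain for prospective biomarker studies combined
    with two-sample Mendelian randomization (MR) of a circulating
    exposure on a binary disease outcome.  Implements summary-statistic
    MR estimators (Wald ratio, fixed-effects inverse-variance weighting,
    correlated-instrument generalized least squares, MR-Egger),
    instrument-strength and power diagnostics, Bayesian enumeration
    colocalization with Wakefield approximate Bayes factors, conditional
    logistic regression utilities for 1:1 incidence-density matched
    case-control sets (sex-specific quintile coding, trend and
    interaction tests, fractional-polynomial non-linearity checks,
    partial rank correlations), and natural direct/indirect effect
    mediation under the nested case-control design.  Seeded generators
    for matched cohorts, two-sample GWAS summary statistics, and LD
    regions provide ground-truth data for calibration and recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
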