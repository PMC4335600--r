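Package: riskometer
Title: Absolute Stroke-Risk Scoring and Model Validation Toolkit
Version: 0.1.0
Authors@R:
    person("Riskometer", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes 5- and 10-year absolute stroke risk with a
    Framingham-style Cox baseline-survival transform, extends it with the
    Stroke Riskometer add-on risk terms (diet, alcohol, physical activity,
    ethnicity, family history, cognition, head injury, anthropometry, prior
    stroke/TIA), and validates any risk score against cohort outcomes:
    ROC/AUROC with DeLong confidence intervals and paired tests, Harrell's
    concordance and Somers' D, Nagelkerke pseudo R-squared,
    Hosmer-Lemeshow calibration, accuracy-targeted classification
    thresholds and high/low cross-tabulation. Includes a seeded synthetic
    cohort generator emulating published cohort marginals and a
    command-line interface for score/simulate/validate/compare workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
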