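Package: riskvalid
Title: External Validation of Cardiovascular Mortality Risk Equations in Older Persons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating fatal cardiovascular risk
    equations (SCORE and SCORE OP families) on participant-level cohort
    data. Computes predicted risks from a declarative coefficient registry
    (two-cause Weibull models with the corrected product combination of
    cause-specific risks, and linear-predictor-on-baseline-survival
    models), derives "actual" event probabilities by Kaplan-Meier
    estimation within the observed follow-up or by Weibull regression
    projection beyond it, and assesses calibration (decile grouping,
    Nam-D'Agostino chi-square, calibration-in-the-large) and
    discrimination (Harrell's concordance index) with bias-corrected and
    accelerated bootstrap intervals. Includes a synthetic cohort
    generator emulating a population-based study of persons aged 70 or
    older, with competing non-cardiovascular death, administrative
    censoring and unknown-cause contamination, so the whole pipeline is
    testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
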