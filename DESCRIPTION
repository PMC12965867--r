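Package: proteintrial
Title: Target Trial Emulation of Dietary Protein Interventions via the
    Parametric G-Formula
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Estimates mean body-composition outcomes in a postmenopausal
    cohort under hypothetical threshold interventions on daily protein
    intake (g per kg body weight per day) using the parametric g-formula
    (g-computation) with nonparametric bootstrap confidence intervals.
    Provides an emulated-trial cohort data model with eligibility
    filtering and censoring accounting, a synthetic cohort generator with
    known counterfactual truth for validation, parametric model fitting
    (linear, logistic, multinomial via nested logits), a Monte Carlo
    standardization engine with a natural-course reference and an exact
    plug-in oracle for discrete cohorts, percentile bootstrap inference,
    and pipeline/reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
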