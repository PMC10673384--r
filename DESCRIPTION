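Package: medscreen
Title: Mediation Screening of High-Dimensional Metabolomics in Longitudinal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A four-step product-method mediation screening workflow for
    untargeted metabolomics in multilevel longitudinal cohort studies.
    Provides quality control for metabolite matrices (missingness, variance
    and log10-transform filters, sample-to-visit matching by age), linear
    mixed models with nested family/individual random intercepts and an
    individual random age slope (via lme4), Benjamini-Hochberg FDR gating of
    exposure-mediator and mediator-outcome screens, product-of-coefficients
    indirect-effect decomposition with Monte-Carlo confidence intervals, and
    a synthetic cohort/metabolome generator with known planted mediation
    structure (including sign-inconsistent suppressor mediators) for testing
    every stage without restricted study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
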