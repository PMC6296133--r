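Package: screenmsm
Title: Non-Homogeneous Multi-State Models for Mammography Screening and
    Overdiagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a non-homogeneous four-state hidden Markov model of breast
    cancer natural history (free of cancer, progressive and non-progressive
    preclinical screen-detectable phases, clinical phase) to individual
    mammography screening histories by maximum likelihood. Transition
    intensities are piecewise constant in age and screening tests are subject
    to imperfect sensitivity with a false-negative carry-forward
    simplification. Provides closed-form transition probabilities, mean
    sojourn time and test sensitivity estimation with Hessian-based standard
    errors, a likelihood ratio comparison against the age-homogeneous model,
    estimation of the expected number of screen-detected non-progressive
    cancers (overdiagnosis) with simulation-based confidence intervals,
    EU-guideline detection-mode descriptives, observed versus expected
    cumulative incidence diagnostics, and a synthetic screening-cohort
    generator with the exact statistical structure the likelihood assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
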