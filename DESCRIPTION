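Package: idmrates
Title: Incidence and Remission Rates from Repeated Cross-Sectional
    Prevalence via the Illness-Death Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates age-, sex- and region-specific incidence and
    remission rates of remitting chronic conditions (such as
    moderate-to-severe anxiety or depressive symptoms) from two
    cross-sectional prevalence surveys combined with general mortality
    rates and condition-specific mortality rate ratios.  The directional
    derivative of a survey-weighted logit-polynomial prevalence surface
    is matched to the illness-death model balance equation, with
    incidence and remission parameterized as Gaussian functions of age
    and estimated by least squares.  Includes a forward cohort solver
    used as a ground-truth oracle, a synthetic-study generator with
    known rates, leave-one-out selection of the age-polynomial degrees
    of freedom, stratified nonparametric bootstrap percentile
    confidence bands, misclassification (Rogan-Gladen) adjustment of
    observed prevalence, and a mortality-rate-ratio perturbation
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
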