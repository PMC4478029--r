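Package: ephcohort
Title: Echocardiographic Pulmonary Hypertension in Population Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives pulmonary artery systolic pressure and left-ventricular
    function measures from per-participant echocardiographic parameters
    (simplified Bernoulli equation, guideline right-atrial-pressure rules,
    fractional shortening, diastolic staging), classifies echocardiographic
    pulmonary hypertension under a primary and two sensitivity definitions,
    and estimates prevalences with Wald confidence intervals overall and by
    subgroup. Covariate missingness is handled by last observation carried
    forward plus chained-equations multiple imputation with predictive mean
    matching, and associations with pulmonary pressure are estimated by
    age/sex-adjusted and multivariable linear models pooled with Rubin's
    rules. A calibrated synthetic-cohort generator reproduces the marginal
    distributions, effect structure and missingness patterns of an elderly
    population-based echocardiography study, so the full pipeline is
    testable end to end without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
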