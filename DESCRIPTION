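Package: popmortgen
Title: Population Mortality (PopMort) File Generation from Abridged Life
    Tables with Relative Survival Validation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts abridged life tables (age-group probabilities of
    dying, nqx) into single-year-of-age population mortality files
    (calendar year x age 0-100 x sex x central mortality rate x annual
    survival probability) of the kind consumed by relative-survival
    software. Implements the classical nqx/nMx interconversion with
    separation factors, piecewise-constant single-age smoothing, midyear
    period assignment with nearest-table carry-forward, delimited readers
    and writers for life tables and PopMort files, a Gompertz-Makeham
    synthetic life-table and cohort simulator, and a minimal actuarial
    observed-survival / Ederer II expected-survival / relative-survival
    estimator with age standardisation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
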