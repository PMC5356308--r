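Package: propmatch
Title: Transported Propensity Scores for Prospective Matched-Cohort Enrollment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing a treatment-initiation propensity score on a
    retrospective electronic-health-record cohort and transporting it to an
    ongoing prospective enrollment stream, where referred patients are matched
    to non-referred controls before treatment begins. Implements logistic
    propensity-score fitting with frozen decile boundaries, temporal validation
    (concordance statistic and calibration), greedy arrival-ordered matching on
    score decile, sex and a patient-reported pain caliper, and covariate-balance
    diagnostics: arcsine and pooled-standard-deviation standardized differences,
    decile-adjusted standardized differences, and the post-matching c-statistic.
    Includes a synthetic chronic-pain cohort generator so the full
    design-feasibility pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
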