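Package: adaptscreen
Title: Adaptive Behavioral Health Diagnostic Screening Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative engine for computerized adaptive diagnostic
    screening instruments: a versioned JSON instrument format (items,
    screening modules, threshold rules, DSM-style criterion and diagnosis
    rules), an adaptive session engine with threshold-gated branching from
    a screener into follow-up sections, scoring from Likert/binary/count
    responses to criterion endorsements and a differential-diagnosis
    report with a symptom severity inventory, and test-retest reliability
    analysis (single-measure absolute-agreement intraclass correlation,
    Cohen's kappa with percentile bootstrap confidence intervals,
    fair/good/excellent interpretation bands, screening-consistency and
    over-endorsement diagnostics). A synthetic-respondent simulator with
    tunable latent severity and cross-occasion reliability makes every
    stage testable without patient data. Ships a fixture instrument
    reproducing the published structure of a 65-item, 13-module screener
    with a 28-entry diagnosis catalog.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
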