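Package: tteval
Title: Empirical Validation of Time-to-Event Model Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Empirical validation of deterministic time-to-event predictions
    against an observed clinical survival curve. Implements bootstrapped
    prediction intervals for Kaplan-Meier curves with the raw-coverage and
    juncture metrics, bootstrapped Fleming-Harrington weighted log-rank tests
    and their MaxCombo combination with a per-iteration proportional-hazards
    diagnostic, an observation-time-uncertainty (OTU) model for the delay
    between a clinical event and its report at the next scheduled visit,
    derivation of time-to-progression from progression-free and overall
    survival event lists, and a synthetic clinical-trial simulator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
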