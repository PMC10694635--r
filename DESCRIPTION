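Package: subvaltest
Title: One-Step Value-Difference Tests for Treatment-Benefit Subgroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for the existence of a patient subgroup that benefits from an
    active treatment versus control, based on the difference between the value of
    an estimated optimal treatment regime and the value of the give-everyone-control
    regime. Inference is carried out with a sequential one-step procedure that
    remains valid at the exceptional law, where the conditional average treatment
    effect is exactly zero with positive probability. Supports uncensored
    continuous outcomes (inverse-probability-weighted and augmented estimators)
    and right-censored time-to-event outcomes on the restricted-mean-survival-time
    scale (including a censoring-augmented doubly robust estimator), two data
    chunking schemes, pluggable nuisance estimators with arm-wise random forest
    defaults, and a simulation harness for type I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
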