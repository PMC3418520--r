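Package: reachadapt
Title: Simulation and Analysis of Trial-by-Trial Adaptation to Sequence Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to study how reaching movements adapt, trial by trial, to
    viscous curl force fields whose amplitude grows in a short predictable
    series. Generates the three-phase experimental protocol (baseline, random
    perturbations with embedded increasing sequences, constant-field blocks),
    simulates minimum-jerk reaches through force fields and error-clamp
    channels for synthetic learners that either average recent perturbations
    or extrapolate their trend, computes adaptation coefficients and
    force-profile measures from channel trials, contrasts post-sequence
    predictions against "average" and "next" benchmarks, and fits
    two-parameter trial-by-trial grip-force models (history-regression and
    weight-variability) compared by variance accounted for.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
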