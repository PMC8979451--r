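Package: dualerror
Title: Dual-Error Models of Implicit Sensorimotor Recalibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how sensory prediction error (SPE) and task
    error (TE) combine to drive trial-by-trial implicit recalibration in
    visuomotor reaching tasks. Implements six candidate learning models
    (Invariant, Rewarded, and Distracted SPE, each with and without an
    additive TE process), generators for error-clamp/target-jump experiment
    schedules with zero-mean perturbation windows, a synthetic-cohort
    simulator with a state-space generative model, the model-free
    trial-to-trial analysis pipeline (outlier exclusion, hand-angle deltas,
    sign normalization, condition medians, per-participant regressions),
    and multi-start bounded least-squares fitting with AIC model comparison,
    participant-level bootstrap confidence intervals, and derived summary
    quantities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
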