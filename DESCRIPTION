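Package: stepgaze
Title: Covert Visual Attention During Obstacle-Crossing Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probing the deployment of covert peripheral visual
    attention while planning obstacle crossing during walking. Implements an
    interleaved 3-down/1-up staircase for orientation-discrimination
    thresholds, balanced cued trial schedules, gaze-fixation quality control
    (2 degree rule), kinematic step-onset detection and obstacle-crossing
    metrics, signal-detection scoring (percent correct, d-prime, beta with
    the log-linear correction) and crossing-minus-stationary change scores,
    and random-intercept linear mixed models with planned Bonferroni-corrected
    contrasts, Cohen's f-squared/d effect sizes and ICC. A synthetic cohort
    generator simulates observers, gaze traces and foot trajectories with the
    statistical structure the analysis assumes, so the full pipeline is
    testable end to end without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
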