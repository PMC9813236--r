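---
title: "Models and methods behind stepgaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stepgaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stepgaze)
```

## The paradigm

`stepgaze` analyses a covert-attention paradigm for obstacle-crossing
planning. An observer fixates a cross on a low obstacle two steps ahead. A
central cue (left/right arrow, or a horizontal bar meaning "stay put")
announces which leg to step with first; 300 ms later a tilted Gabor patch
flashes for 77.8 ms at one of four walkway locations (R1, L1, R2, L2 — the
candidate first- and second-step landing spots for each leg), and the
observer verbally reports its tilt while initiating the crossing (or
remaining stationary). The cue defines which two locations are *stepping*
locations (right arrow: R1 and L2) and which are *non-stepping*; the
horizontal bar makes relevance inapplicable. Discrimination accuracy per
relevance-by-step cell, referenced against the stationary baseline, indexes
where covert attention is deployed while the step sequence is being planned.

The package implements the full analysis chain — adaptive thresholding,
schedule construction, gaze and timing quality control, kinematic event
detection, signal-detection scoring, and mixed-model inference — plus a
synthetic cohort generator with the statistical structure the analysis
assumes, so every stage is testable end to end without recordings.

## Adaptive thresholding

Orientation thresholds are estimated per location with an interleaved
3-down/1-up transformed staircase: step 0.3°, start 6°, termination at the
sixth reversal, threshold = mean of the last four reversal levels. The rule
equilibrates where three consecutive correct responses are as likely as
not, i.e. at `p = 0.5^(1/3) = 0.794` ("79%").

Conventions the protocol leaves open, fixed here:

* the 3-correct counter resets after **every** adjustment (standard
  transformed up-down convention);
* a *reversal level* is the level adjusted **away from** at a direction
  change; the first adjustment has no direction history, so the first
  reversal requires one prior adjustment;
* levels are floored one step above zero (0.3°); a down-move at the floor
  holds the level but still counts as a downward adjustment, so a perfect
  responder still accrues reversals on later errors instead of running
  forever.

**Estimator behaviour.** Long-run simulation shows the mean reversal level
is essentially unbiased: with a cumulative-Gaussian observer the true
psychometric function evaluated at the mean of late reversals sits at
0.79. With only six reversals and a start level far above the observer's
threshold, however, the estimate retains a positive *transient* bias
(about +0.3–0.5° for a threshold near 4° and slope 1.5°), because early
reversals happen while the track is still descending. The package's
convergence validation therefore uses an observer whose true 79.4%-correct
orientation equals the 6° starting level, where the run operates in its
stationary regime; recovery of thresholds in the 3–4.5° range is validated
at the level of rank order of run-averaged estimates instead. Users running
real sessions with thresholds well below 6° should expect the same modest
conservative (higher-orientation) bias the original protocol carries.

## The synthetic observer and cohort

The observer couples two descriptions, deliberately decoupled so the two
test surfaces do not share a code path:

* a per-location cumulative-Gaussian psychometric function over orientation
  magnitude, `p(x) = 0.5 + (0.5 - lapse) * pnorm((x - mu)/slope)`,
  parameterised by the orientation of its 79.4% point (defaults: the group
  thresholds 4.3°/4.0°/3.6°/3.2° at L1/R1/L2/R2, slope 1.5°, lapse 0.02)
  — used by the staircase;
* per-cell response probabilities for the experimental session: a
  stationary baseline of 0.90 per location ("close to 90%" stationary
  performance), reduced by an attention deficit of 7.3 percentage points at
  the cells named in a modulation map — by default only (stepping, step 1)
  on crossing trials, the paradigm's headline effect.

A cohort adds two Gaussian participant effects: a baseline intercept
(SD 3 points, shifting all cells) and a *crossing shift* (SD `sqrt(6.344)`
points, shifting only crossing cells). The crossing shift is the component
that survives crossing-minus-stationary subtraction; its variance is set so
the change-score mixed model's ICC lands near the 0.23 the paradigm
reports, given the binomial trial noise at 48 trials per cell. Responses
are conditionally independent given the participant — the generator models
no trial-to-trial serial dependence.

Gaze traces are zero-mean Gaussian fixational noise (SD 0.3° per plane,
120 Hz) over the fixation-to-cross-offset window, with rare injected
saccade-like excursions (default rate 0.001, magnitude 3.5°) reproducing
the ~0.1% fixation-exclusion rate. Foot-marker trajectories (100 Hz) are
flat up to an embedded step onset drawn from Normal(741, 105) ms truncated
to the (377.8, 1000] ms validity window (plus deliberate too-fast/too-slow
violations at rates 0.0007/0.0059), then follow raised-cosine swing arcs
realising drawn step placements and obstacle clearances; the crossing
swing's apex sits exactly above the obstacle's front edge at the drawn
clearance. Every simulated quantity is emitted in a ground-truth ledger so
recovery tests compare detector output against the embedded truth, never
against a re-simulation.

Two constructional choices matter for detector testing. Onsets are snapped
to the 10 ms sampling grid and movement begins one sample *before* the
embedded onset with a brisk 1 cm initial displacement, so the 0.5 cm
deviation threshold is first satisfied exactly at the embedded onset
sample: the detector is then exactly grid-unbiased and its recovery can be
asserted to one sample. And because the upper truncation bound (1000 ms)
is closer to the mean than the lower one, the truncated-onset expectation
is ~739 ms rather than 741 ms; recovery tests compare against the
truncated-distribution mean in closed form.

What the generator does **not** emulate: biomechanically realistic gait
(mass, balance, double support), binocular gaze geometry, serial
dependence or learning across trials, response-time structure, and any
perceptual interaction between walking state and the psychometric slope
(the deficit is imposed directly on cell probabilities). Passing tests
therefore certify the *analysis chain* — detection, scoring, inference —
under the assumed statistical structure, not the psychology of real
walkers.

## Quality control and kinematic events

Fixation compliance recomputes the per-sample angular deviation from the
initial fixation direction — by default the mean gaze over the window's
first 100 ms, damping tracker noise; a single-sample reference is
available. "Deviated by more than 2° in any direction" is ambiguous
between per-plane and composed readings; the default thresholds the
composed magnitude `sqrt(h^2 + v^2)` (the stricter reading), with a
per-plane mode provided. Exactly 2.0° passes ("more than" is strict).

Step onset is the first sample deviating at least 0.5 cm forward or upward
from the cue-onset position (the comparison is `>=`, matching "of at least
0.5 cm"). Onsets at or below 377.8 ms are too fast; above 1000 ms too
slow. The two printed bounds for the fast cutoff differ by 0.1 ms in the
protocol text; validity here is `onset > 377.8`.

Obstacle metrics: the crossing instant is found by linear interpolation on
the forward axis between the samples straddling the obstacle's front edge;
clearance is the interpolated height minus the 5 cm obstacle height
(negative clearance flags contact). Horizontal distance is the obstacle
position minus the midstance forward position of the stance preceding
crossing. *Stance* is not defined by the protocol; here it is a maximal
contiguous interval with planar foot speed below 2 cm/s and height within
1 cm of the interval minimum, and *midstance* its temporal midpoint —
deterministic and robust on synthetic traces. Foot placement is the planar
Euclidean distance between the midstance position and the Gabor centre.

## Signal-detection scoring

Right-tilted patches are arbitrarily the "signal": correct/incorrect
responses to right tilts are hits/misses, to left tilts correct
rejections/false alarms. Percent correct uses raw counts. Hit and
false-alarm rates apply the log-linear rule — add 0.5 to the numerator and
1 to the denominator — *unconditionally* to every cell, not only perfect
ones, keeping rates strictly inside (0, 1), the normal quantiles finite,
and the cell ordering intact. Sensitivity is `d' = Z(hit) - Z(fa)`; the
response criterion is the likelihood ratio
`beta = exp((Z_fa^2 - Z_hit^2)/2)`, which reproduces the anchor
behaviours: 1 for an unbiased responder, below 1 for a "right"-biased one.
Crossing trials are binned into the four relevance-by-step cells and
stationary trials by step only; change scores subtract the step-matched
stationary score from each crossing cell.

## Mixed-model inference

Each change-score outcome is modelled as
`delta ~ relevance + step (+ relevance:step) + (1 | participant)` by
maximum likelihood, treatment-coded with referents *stepping* and
*step 1*. The interaction is retained only when its Wald test is
significant (p < 0.05) **and** the interaction model has the lower AIC.
Wald 95% intervals and p-values use Satterthwaite degrees of freedom
(via lmerTest); ICC is the intercept share of the two variance
components; marginal and conditional R² use the variance-partition
definitions. Four planned comparisons — first stepping location against
the second stepping and both non-stepping locations, plus second stepping
against second non-stepping — are evaluated at the Bonferroni-corrected
alpha of 0.013. Cohen's d for contrasts divides the difference by the
square root of the total outcome variance (intercept + residual); for
change-vs-zero tests it divides the model-based cell mean by the
between-participant SD of that cell's raw change scores. Cohen's f² is
`R2m/(1 - R2m)` for a model and `(R2m_full - R2m_reduced)/(1 - R2m_full)`
for a dropped effect. Cell means and their intervals come from linear
combinations of the fixed effects (equivalent to re-referencing the
intercept), so the "does the interval cross zero" test matches the
intercept test of a refit with that cell as referent.

**A calibration caveat inherent to the design.** Both relevance cells of a
step subtract the *same* stationary score, so change-score residuals are
positively correlated within a step. A single random intercept cannot
represent that heterogeneous covariance: simulation with the null
generator shows the across-step planned contrasts run anti-conservative
(roughly 3–6% each at the 0.013 level) while within-step contrasts are
conservative, lifting the familywise false-positive rate over the four
comparisons to roughly 7–8% rather than the ≤5% a Bonferroni argument
would suggest. The contrast machinery itself is calibrated — under data
that satisfy the model's assumptions the familywise rate is under 5% —
so this is a property of pairing shared-baseline change scores with a
random-intercept-only model, worth knowing when interpreting borderline
across-step comparisons.

## Problem sizes and numerical choices

Simulation-backed tests use sizes chosen to keep Monte-Carlo error well
inside the asserted margins: 500 staircase runs for the convergence check,
2000 trajectories for detector unbiasedness, 200 cohort replicates for
deficit recovery, 500 for null calibration, and 100–250 replicates for
module-level calibration oracles. Cohort replicates for calibration runs
simulate the response pathway only (`traces = "none"`); trace-dependent
stages are exercised by the construction and recovery tests. Other
numerical choices: truncated-normal draws by inverse-CDF; probabilities
clamped to [0.005, 1] after participant shifts; degenerate SDT cells
(no signal or no noise trials) fall back to a corrected rate of 0.5 with a
warning; singular mixed-model fits (zero intercept variance) succeed with
a warning rather than failing.

## Limitations

Real data enter as tidy tables (responses, long gaze, long kinematics);
vendor eye-tracker and motion-capture formats are out of scope, as are
stimulus rendering, workload questionnaires, and simulation-based residual
diagnostics beyond QQ and residual-vs-fitted plots. The generator's
defaults describe one published cohort; transferring conclusions to other
populations requires re-estimating baselines, deficits and variance
components.
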