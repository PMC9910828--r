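---
title: "Quantifying reward effects on sensorimotor feedback responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reward effects on sensorimotor feedback responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgreward)
```

## The scientific problem

When a reaching movement is perturbed — mechanically (a torque applied at
the elbow or shoulder) or visually (the cursor or the goal target jumps) —
the nervous system produces corrective *feedback responses* visible in
surface EMG within tens of milliseconds. These responses form a hierarchy:
a short-latency stretch response (SLR, ~25 ms, spinal), a long-latency
response (LLR, ~50 ms, transcortical and goal-sensitive), target-selection
responses (~100 ms) and visuomotor responses to cursor or target jumps
(~120 ms). `emgreward` implements an analysis pipeline for asking whether
the *prospect of monetary reward* changes these responses, and if so
whether it shortens their latency, increases their gain, or both.

Two quantities are estimated per participant and reward condition:

* **Divergence latency** — the first time at which the EMG distributions of
  two contrasted trial sets separate. At every sample we compute the ROC
  area under the curve (AUC) between the two sets, using all trials without
  averaging: the probability that a random trial from one set exceeds a
  random trial from the other, ties counting 1/2. The threshold band is
  25–75%; it counts as reached when two consecutive samples lie beyond it.
  A two-segment linear regression is then fitted to the AUC before the
  crossing, minimizing the summed squared residuals over all candidate
  breakpoints; the breakpoint is the response latency.
* **Feedback gain** — the absolute difference between the trapezoid-rule
  integrals of the two condition-mean EMG traces, in a window that starts
  at that participant's *own* latency (width 50 ms, narrowed to 25 ms for
  the SLR contrast to avoid overlapping the LLR). Reward modulation is
  summarized by the log-ratio `G = ln(gain_rewarded / gain_non_rewarded)`.
  Anchoring the window at the measured latency matters: with a fixed
  window, a latency shift would masquerade as a gain change, because the
  EMG has had more time to diverge by the time the window opens.

Group-level inference uses paired Wilcoxon signed-rank tests with the
common-language effect size `r = W / (n(n+1)/2)` — the proportion of the
maximal rank sum carried by positive differences — reported alongside `W`,
`n` and the two-sided `p`.

## Task designs

Five factorial task designs are shipped as plain-text configuration files
(`inst/extdata/designs/`): In-Out Target (336 trials, 3 blocks), Target
Selection (224 trials, half with two targets), Cursor Jump and Target Jump
(312 trials each), and Proprioception-cued Reaction Time (108 trials).
Trials are organized in epochs containing exactly two of each factor
combination, with order randomized independently within each epoch;
`make_schedule()` is a pure function of the design and a seed.

Rewarded trials pay a return in cents. The In-Out task pays on the time
`x` (ms) the cursor occupies the target between perturbation onset and
trial end,

$$\mathrm{return} = g\,e^{-\tau p}, \qquad
  p = 1 - \min\!\left(\frac{x - x_0}{x_f - x_0},\, 1\right),$$

with `g = 15`, `x0 = 500`, `xf = 800` and a per-condition `tau`. The other
tasks pay on movement time,

$$\mathrm{return} = \max\!\left(g\,(\mathrm{scaler}\,e^{-\tau p} +
  \mathrm{shifter}),\, 0\right), \qquad p = \mathrm{MT}/\mathrm{MT_{max}},$$

with per-condition calibration constants stored in the design files. Two
readings of the second formula are possible (`shifter` inside or outside
the factor of `g`); we place it inside because `scaler` and `shifter` are
commensurate dimensionless calibration constants, and the Reaction-Time
parameters (`scaler = 1`, `shifter = 0`) make the headline maximum (10 ¢)
identical under either reading. Similarly, the time-in-target formula is
evaluated as printed for all `x >= 0`; `x0` is not treated as a hard
zero-return floor. Accumulated (not necessarily contiguous) target
occupancy counts toward `x`.

Movement time is task-specific: from perturbation onset to target entry
regardless of velocity (proprioceptive tasks), or from leaving the start
position to being inside the target with radial speed below 10 cm/s
(visual tasks), with radial velocity taken from centered finite
differences. Target Selection uses the proprioceptive rule with the
*correct* target. Logged mechanical perturbation timestamps precede the
actual limb acceleration by 4 ms on this apparatus, so all
perturbation-locked analyses shift the event by that constant; visual
events use photodiode-corrected timestamps as stored.

## EMG conditioning chain

The chain is fixed: band-pass, full-wave rectification, normalization.

* **Band-pass 20–250 Hz.** A 4th-order Butterworth applied
  forward-backward. Zero phase is essential: any group delay would bias
  every latency in the study. The series mean is removed first (DC lies
  outside the passband) and the series is extended by odd reflection
  before the two passes; the first and last ~50 ms are still treated as
  transient and kept out of analysis windows.
* **Normalization.** Before each task, four 2-s static holds are recorded.
  Each hold is trimmed to 250 ms after start-position entry through 250 ms
  before the end of the window (1500 ms), concatenated (6000 samples at
  1000 Hz) and averaged per muscle; task EMG is divided by this scalar.
* **Trial baseline.** Mean and SD of the processed EMG in the half-open
  window [−350, −300) ms before the design's baseline event (displacement
  onset, or target appearance in the jump tasks where displacements occur
  mid-movement). The SD is the across-sample SD within the single trial's
  window: the reaction-time criterion speaks of the *trial* baseline
  level, which supports a within-trial reading.

Reaction times (Proprioception-cued RT task) are detected when the
processed triceps EMG stays strictly above `baseline mean + 3 SD` for 5
consecutive milliseconds; trials never meeting the criterion are discarded
rather than imputed.

## The synthetic-data generator

No recordings ship with the package. `simulate_dataset()` generates
complete datasets — calibration holds, per-trial five-muscle EMG at
1000 Hz, radial kinematics, movement times — with every generated
parameter stored as ground truth, so each analysis stage can be validated
by parameter recovery.

Raw EMG is modelled as a zero-mean band-limited Gaussian carrier
(30–200 Hz) multiplied by a non-negative envelope, plus broadband sensor
noise. This choice — rather than simulating already-rectified traces —
means the package's own filtering and rectification are genuinely
exercised: after the chain, the across-trial mean converges to the
envelope expressed in calibration units. The envelope is a tonic baseline
(the loaded extensors sit higher than the flexors) plus evoked components
with a half-Gaussian rise (SD 10 ms) to a plateau and a half-Gaussian
decay. Stretch-response components are transient (25 ms plateau);
goal-dependent and visuomotor components are sustained. Amplitudes carry
log-normal trial-to-trial jitter (SD 0.2) so ROC discrimination is
non-degenerate, and per-participant random effects (evoked gain, MT/RT
offsets, a small latency offset) make paired across-participant tests
meaningful. Kinematics are minimum-jerk radial profiles parameterized by
the ground-truth movement time; they support the MT definitions but carry
no joint-space dynamics.

Reward effects enter as ground truth: a multiplicative evoked-amplitude
factor (`reward_gain_factor`, default 1.25, i.e. true `G = ln 1.25`), a
movement-time reduction (30 ms) and a reaction-time reduction (12 ms).
The defaults are chosen to be physiologically plausible and to make the
estimators' tolerances meaningful; the study's real signal-to-noise
figures are unknown, so passing recovery tests shows the estimators are
correct and well-calibrated *under this noise model*, not that the
original recordings would yield identical numbers. Two deliberate
calibrations deserve note. First, under the Gaussian-carrier model the
per-sample AUC between two envelopes `E_a`, `E_b` is approximately
`(2/pi) atan(E_a/E_b)`, so a contrast only crosses the 0.75 threshold when
the envelope ratio exceeds ~2.4; evoked amplitudes default to ~3x the
tonic baseline so that contrasts are detectable, and a muscle without an
evoked component correctly yields no crossing (an invalid latency, as
with muscles that carry no response in practice). Second, the RT-task
movement burst is large (40x the low tonic baseline) and steep (rise SD
2 ms), as ballistic bursts are; at these values the two opposing detector
distortions — the zero-phase filter smearing burst energy ~1–2 ms
backward, and the 5-ms run criterion delaying detection past rectified
carrier dips — roughly cancel, keeping the median detection error within
the ±2 ms recovery tolerance the test suite asserts. A slow small burst
would make *any* threshold detector biased; that bound is a property of
the criterion, not of its implementation.

A master seed expands into per-participant and per-trial streams through a
Lehmer-style counter scheme, so a fixed seed yields byte-identical
datasets and any subset can be regenerated independently. Datasets can be
written to and read from a documented plain-text layout (a trial manifest
CSV plus one time-series CSV per trial with a provenance header), which is
also the entry point for real recordings.

## Numerical and design choices

* ROC analysis window: [−100, +300] ms around the alignment event;
  pre-event samples anchor the flat regression segment. The pre-crossing
  fit starts at t = 0 for mechanical contrasts (pre-perturbation activity
  is tonic) and at the window start for visual contrasts.
* Segmented regression: two independent lines (not constrained to join),
  minimum 3 samples per segment, candidate breakpoints searched
  exhaustively at 1-ms resolution, SSE ties broken toward the earliest
  breakpoint (conservative latency). The breakpoint sample belongs to both
  segments.
* Crossing band symmetric: two consecutive samples strictly above 0.75 or
  strictly below 0.25 both count, so inhibitory contrasts are detected.
* Trials with the target in the perturbation direction are included in the
  SLR contrast.
* Gains integrate per-participant condition-mean traces at 1-ms spacing
  (trapezoid rule); in the RT task the window is anchored at each trial's
  own reaction time, the integral taken per trial and then averaged,
  because reaction time varies trial to trial. Gain units are
  normalized-EMG x ms; only ratios are interpreted. Non-positive gains
  leave `G` undefined; such pairs are excluded from the paired statistics
  with a logged count.
* Signed-rank test: zero differences dropped, midranks for ties (so `W`
  may be half-integer), exact two-sided p by convolution of the signed-rank
  null distribution for n <= 25 (valid under midrank ties), normal
  approximation with tie and continuity corrections above. No
  multiple-testing correction is applied; per-muscle tests are reported
  raw.
* The effect size `r = W / (n(n+1)/2)` reproduces all 46 reported
  `(W, n, r)` triples bundled as a fixture at two decimals
  (`inst/extdata/printed_signed_rank_triples.csv`).

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
per-sample AUC against exhaustive pairwise counting, the segmented fit
against an `lm()`-based exhaustive breakpoint search, the exact
signed-rank p against full 2^n sign enumeration (n <= 10) and against
`wilcox.test` where no ties occur, and the trapezoid integral against a
fine-grid Riemann sum. Stochastic properties use fixed seeds and these
problem sizes, chosen to keep a full run comfortably on a laptop:

* latency recovery: injected 25/50/100-ms latencies, 100 seeds, 50
  trials per side, median error within ±3 ms;
* gain recovery: `rho` in {1, 1.25, 2}, 24 participants x 64 trials per
  cell, median estimated `G` within ±0.05 of `ln rho`, and monotone in
  `rho`. The injected component for this check uses a sharper onset (rise
  SD 3 ms) so the latency-anchored window sits on the response plateau:
  with the default 10-ms rise the window overlaps the rise and `G`
  inherits substantial per-participant latency-estimation noise — a
  property of the windowing method itself, not of the integrator under
  test;
* null calibration: 100 end-to-end pipeline runs with no reward effect
  (8 participants, 4 epochs, triceps only), requiring false-positive
  counts at alpha = 0.05 to stay at or below 10/100 for each test;
* RT detection: median recovery error within ±2 ms over 60 trials, and
  4-ms supra-threshold blips never accepted.

## Known limitations

* The generator's carrier model fixes the rectified signal's
  coefficient of variation (~0.75); real EMG can be less or more variable,
  so absolute power figures here do not transfer to real recordings.
* Latency estimates carry a few milliseconds of spread at realistic trial
  counts; contrasts whose envelope ratio stays below ~2.4 never cross the
  AUC band and are reported as invalid rather than guessed.
* Kinematics are schematic (1-D radial minimum-jerk); they exist to
  exercise the movement-time definitions, not to model limb dynamics.
* The pipeline reports per-participant tables and group tests; it does not
  compute group-level latency confidence intervals beyond descriptive
  statistics, and offers no Bayesian changepoint alternative.

## A minimal end-to-end run

```{r example, eval = FALSE}
design <- task_design("in_out")
config <- synth_config(design, n_participants = 8,
                       muscles = "triceps_lat",
                       baseline_level = c(triceps_lat = 1),
                       max_epochs = 4, seed = 11)
dataset <- simulate_dataset(design, config)
report <- run_pipeline(dataset, contrast = "slr")
print(report)
```

The report prints the movement-time contrast, the paired latency test, the
per-muscle gain log-ratios with their signed-rank tests, and (for the
In-Out task) the anticipatory-EMG control check. `write_report()` persists
the underlying tables as CSV and the test summaries as JSON.
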