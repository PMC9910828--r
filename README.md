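# emgreward

Tools for studying how the prospect of monetary reward modulates
sensorimotor feedback responses measured with surface EMG.

When a reach is perturbed — a torque at the elbow, a cursor or target jump
— corrective responses appear in the EMG within tens of milliseconds,
from the spinal short-latency stretch response (~25 ms) through the
long-latency response (~50 ms) to target-selection (~100 ms) and
visuomotor (~120 ms) responses. This package implements a complete,
tested pipeline for asking whether reward shortens the *latency* of these
responses, increases their *gain*, or both:

* five robot-based task designs (In-Out Target, Target Selection, Cursor
  Jump, Target Jump, Proprioception-cued Reaction Time) with factorial,
  epoch-randomized trial schedules and per-condition monetary-return
  functions;
* the EMG conditioning chain: zero-phase 20–250 Hz Butterworth band-pass,
  full-wave rectification, normalization by per-muscle scalars from four
  2-s calibration holds, event alignment (including the 4-ms mechanical
  perturbation-onset correction) and trial-baseline statistics;
* response-latency estimation as the divergence time of two trial sets:
  per-sample ROC discrimination (Mann–Whitney AUC over all trials,
  without averaging), a sustained 25–75 % threshold crossing (two
  consecutive samples), and a two-segment least-squares regression whose
  SSE-minimizing breakpoint is the latency;
* feedback gains as the absolute difference of trapezoid-integrated
  condition-mean EMG in a window anchored at each participant's own
  latency (25 ms for the SLR contrast, 50 ms otherwise), summarized by the
  reward log-ratio `G = ln(gain_rewarded / gain_non_rewarded)`;
* EMG-based reaction-time detection (3 SD above the trial baseline for
  5 ms in a row, non-conforming trials discarded);
* paired Wilcoxon signed-rank tests (exact for n ≤ 25, valid under
  midrank ties) with the common-language effect size
  `r = W / (n(n+1)/2)`;
* a synthetic-data generator (band-limited Gaussian carrier x envelope)
  with full ground truth, so every stage is validated by parameter
  recovery without any recordings, plus a documented plain-text
  manifest + time-series on-disk layout for real data.

## Worked example

Simulate an In-Out Target dataset (8 participants, the full 336-trial
schedule, triceps only; ~12 s) and run the short-latency
stretch-response analysis:

```r
library(emgreward)

design  <- task_design("in_out")
config  <- synth_config(design, n_participants = 8,
                        muscles = "triceps_lat",
                        baseline_level = c(triceps_lat = 1),
                        seed = 11)
dataset <- simulate_dataset(design, config)
report  <- run_pipeline(dataset, contrast = "slr")
report
```

```
Reward-feedback report: task 'in_out', contrast 'slr', 8 participants
  Movement time (rewarded - non-rewarded): median diff -29.5 ms; W = 0, r = 0.00, p = 0.00781 (n = 8)
  Latency (paired across reward): W = 18.5, r = 0.51, p = 0.992 (n = 8) [8 valid pairs]
  Gain triceps_lat:     median G = +0.257; W = 26, r = 0.72, p = 0.312 (n = 8)
  Anticipatory EMG (rewarded): W = 16, r = 0.44, p = 0.844 (n = 8)
  Anticipatory EMG (non_rewarded): W = 9, r = 0.25, p = 0.25 (n = 8)
```

Reading the report: rewarded movements are ~30 ms faster (the generator's
built-in reward effect; every participant's median moved the same way, so
`W = 0` and `r = 0`); response latencies do not differ between reward
conditions (none was simulated, `r = 0.51`); the median gain log-ratio
(+0.26) sits near the generator's ground truth `ln 1.25 ≈ 0.22` though
the paired test is underpowered at 8 participants; and the
anticipatory-EMG control check finds no pre-perturbation difference.
`write_report(report, "out/")` writes the per-participant tables (CSV)
and test summaries (JSON).

Per-stage functions are exported too — `make_schedule()`,
`in_out_return()` / `mt_return()`, `bandpass()`, `normalization_scalar()`,
`auc_trace()`, `segmented_fit()`, `estimate_latency()`,
`feedback_gain()`, `detect_reaction_time()`, `signed_rank()` — see the
vignette (`vignettes/reward-feedback-analysis.Rmd`) for the model, its
assumptions and all numerical choices.

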