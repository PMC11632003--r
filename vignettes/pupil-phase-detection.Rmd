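---
title: "Streaming detection of pupil phase events: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming detection of pupil phase events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilphase)
```

## The problem

Under constant luminance the pupil fluctuates spontaneously — *pupillary
unrest* — with a dominant rhythm near 0.5 Hz. The fluctuation cycles
through four phases: dilation, peak (local maximum), constriction, trough
(local minimum). Because these phases lag central arousal-related neural
activity by only ~0.1 s, detecting them *as they happen* enables
closed-loop experiments (stimulus delivery locked to pupil state,
neurofeedback) that retrospective pupillometry cannot support.

The difficulty is that pupil size is sluggish, drifts over seconds, and is
interrupted by blinks. A fixed threshold on size or slope fails as the
baseline wanders; `pupilphase` instead re-estimates subject-specific
percentile thresholds every few seconds from the subject's own recent
data.

## The four-stage streaming algorithm

`run_detector()` consumes timestamped samples and applies:

1. **Ingestion.** Samples accumulate into *pupil samples* of 0.1 s.
   Durations are judged by cumulative inter-sample interval (each sample
   carries the interval ending at it), so irregular online rates are
   handled; at a fixed 60 Hz a pupil sample is 6 points. The dialect's
   missing sentinel (0 for video trackers, negative values for the mouse
   preparation) becomes `NaN` here.
2. **Windowing.** Each pupil sample is appended to a *search window*
   (analysed for events) and a *baseline window* (used to refresh
   thresholds). A search window containing any `NaN` is cleared, and the
   window after a contaminated one is cleared as well, so no fit ever sees
   data adjacent to an artifact. The baseline window accumulates
   regardless.
3. **Modelling.** Once the search window holds two pupil samples it is
   demeaned and fit with a quadratic over abscissae `0..n-1`
   (`fit_search_window()`); the fitted value at the final abscissa (the
   *final value*) summarises where the window is heading.
4. **Classification.** Successive final values are compared
   (`classify_phase()`): a peak is a downturn above the peak-size
   threshold; a trough an upturn below the trough-size threshold; dilation
   and constriction are final-value jumps beyond the derivative
   thresholds. Rules are evaluated in the fixed order peak, trough,
   dilation, constriction, so each fit emits at most one event. Whenever
   the baseline window fills (5 s human/mouse, 0.5 s monkey) and at least
   half its samples are valid, the four thresholds are re-estimated:
   peak/trough sizes from the 75th/25th percentile of local-extremum
   values of the demeaned window, derivative bounds from the 99th/1st
   percentile of its successive differences (troughs are located on the
   negated series; their values are read from the original one).
   Percentiles interpolate linearly between order statistics.

Detections are *accepted* only if they fall more than the inter-event
interval (IEI; 3 s human, 1 s mouse, 1.5 s per event type in the monkey
preset) after the previous accepted event; closer detections are logged
with `accepted = FALSE`. Phase-independent *random* control events are
scheduled as a renewal process with gaps `IEI + Exponential(rate)` — the
minimal mechanism that is blind to the data while honouring the IEI.

### Window-clearing policy

Two readings of the gating rule are defensible, and the package keeps both
behind `clear_on_rejected`. The default clears the search window after
*every* detection: each fit lineage then starts fresh, the window stays
short and responsive, and detection latencies stay well inside the
±0.25 s tolerance used by the evaluation. The alternative
(`clear_on_rejected = FALSE`) clears only on accepted events and lets the
window accumulate after rejected ones; in our simulations that reading
produces long, sluggish windows whose quadratic end-point turns 0.3–0.4 s
after a true extremum and starves peak/trough detections, which is why it
is not the default. For the same reason the previous final value is
discarded whenever the window is cleared — comparisons are only ever made
within one window lineage.

### Startup

Until the first valid baseline update the thresholds are fixed constants
(peak 0, trough 0, dilation +50, constriction −50 in device units). With
a demeaned signal these block sub-zero peaks and supra-zero troughs, so
the first seconds of a recording yield mostly derivative-based events.

## The replay simulator

`replay()` streams a recorded (or synthetic) series through the identical
detector code path, with species presets reflecting the published
parameter sets (`species_preset()`):

* **human** — the 1000 Hz offline recording is decimated to the ~60 Hz
  online rate by pure index selection (`resample_to_online_rate()`);
  emulating the online sampling is the goal, so no anti-alias filtering
  is applied.
* **mouse** — locomotion-concurrent and negative samples are masked to
  `NaN` first (`mask_mouse_artifacts()`); ~20 Hz, 1 s IEI.
* **monkey** — trial segments longer than 5 s are selected, each segment
  is artifact-cleaned by interpolation, and the detector runs per segment
  with all state reset between trials (they are noncontiguous); 0.5 s
  baseline and a 1.5 s IEI applied within each event kind.

Real trackers filter their saved traces more heavily than the real-time
link stream; `online_noise_sd` optionally adds white acquisition jitter to
the replayed stream (leaving blink zeros intact) to emulate live-link
conditions. Pure replay (`online_noise_sd = 0`) is the default.

## The synthetic cohort

`generate_unrest()` simulates a recording as a sum of sinusoids plus a
Gaussian random-walk drift and white measurement jitter, offset to a
positive baseline, with blinks injected as runs of the zero sentinel.
Defaults (chosen once as the package's study conditions):

| parameter | default | rationale |
|---|---|---|
| components | 120/25/8/3 a.u. at 0.5/1.1/2.2/3.4 Hz | dominant ~0.5 Hz unrest with a steep spectral fall-off into the evoked range |
| `drift_sd` | 5 a.u./√s | baseline wanders by ~100 a.u. over minutes |
| `noise_sd` | 0.2 a.u. | file-grade traces are smooth at the sample scale on research trackers |
| `blink_rate`, durations | 0.1 /s, U(0.1, 0.3) s | typical spontaneous blinking |
| baseline | 3000 a.u. | pupil-area-like device units |

The amplitude fall-off and the two noise scales were set so the simulated
recordings reproduce two observable properties of real evaluations: the
prominence-filtered extrema density (~1.2 events/s, giving the ±0.25 s
truth windows ~50% coverage, which is exactly the random-event baseline
reported for real data), and balanced counts of all four accepted event
kinds once link-level jitter (10 a.u.) is added at replay. They were not
adjusted against the package's own test thresholds.

`make_cohort()` derives per-subject seeds deterministically and varies
phases, amplitudes (±25%) and frequencies (±10%) across subjects, so
subject signals decorrelate on average while keeping the ~0.5 Hz
character. The analytic ground truth (noise-free component sum, its
root-refined extrema times and gradient sign) travels with each
recording.

What the generator does *not* emulate: luminance responses, the
biomechanical asymmetry of dilation vs constriction speed, non-stationary
blink bursts, gaze-dependent foreshortening, or tracker dropouts longer
than a blink. Passing tests on this cohort therefore show the pipeline is
correct and well-calibrated for unrest-like signals, not that the
published real-data accuracies transfer to any particular laboratory
setup.

## Ground truth and performance metrics

The evaluation emulates the published design: detection runs on the
online-rate stream, but truth is computed from the full-rate offline
series, where `smooth_for_truth()`'s 0.1 s Savitzky–Golay window spans
101 samples and suppresses measurement noise. (At 60 Hz the same window
is 7 samples and cannot separate noise wiggles from genuine extrema — a
reason to keep offline recordings at the acquisition rate.)

* `preprocess_pupil()` locates sentinel/`NaN` runs, dilates them by a
  50 ms margin per side (the distorted shoulder around lid closure), and
  interpolates linearly.
* `true_extrema_index()` finds local maxima, ranks them by topographic
  prominence, keeps the most prominent 75% (prominence at or above the
  25th-percentile prominence, ties kept), and marks ±0.25 s around each
  kept event; troughs identically on the negated series. Recordings with
  many shallow extrema may warrant a stricter keep fraction — the
  parameter is exposed.
* `true_gradient_index()` labels each sample dilation (positive
  central-difference slope) or constriction (negative); zero-slope
  samples belong to neither.
* `event_accuracy()` / `sensitivity_matrix()` score accepted events
  against each index; `accuracy_tests()` runs the paired (vs random) and
  one-sample (on- minus off-target) t-test families with Holm–Bonferroni
  adjustment within each family of four.
* `temporal_performance()` pools *all* detected phase events (accepted or
  not; random events excluded), drops inter-event gaps that span block
  boundaries, and reports per-subject medians, the group median, and its
  reciprocal as the detection rate.
* `detect_saccades()` is a deliberately simplified velocity-threshold
  detector (±2-sample central-difference velocity, median-based SD,
  elliptic criterion at λ = 6, runs ≥ 3 samples) — plumbing for the
  eye-movement control analysis, not a reference implementation.

## Epochs and cluster statistics

`extract_epochs()` cuts windows of ±2.5 s (5001 samples at 1000 Hz;
±0.5 s, 1001 samples, for monkey trials) around event times, skipping
events whose window would cross a recording edge, and demeans pupil
epochs; `detrend_epochs()` additionally removes a per-epoch line (monkey
drift). Group curves average per-subject means, optionally z-scoring each
subject curve over its own time axis first (the chosen reading of the
ambiguous "z-score across participant time courses"; standardizing per
time point across participants remains possible by operating on
`subject_curves` directly). Binary blink/saccade epochs become
occurrence-fraction curves; saccade curves take a 0.1 s moving average.

`cluster_permutation_test()` compares paired subject curves: pointwise
one-sample t on the differences, clusters formed by temporal adjacency
above the two-tailed t quantile at α = 0.05 (n−1 df; the cluster-forming
threshold is otherwise unstated in the original procedure), cluster mass
= summed t. The null flips the sign of whole subject difference curves;
with n ≤ 10 subjects all 2^n flips are enumerated (an exact null at the
cost of 256 evaluations for n = 8) instead of 250 random draws. Each
observed cluster is referred to the per-permutation extreme magnitude
over both tails, which keeps the two-tailed family-wise error at the
nominal level; with random draws the add-one convention bounds p away
from zero. Positive and negative null distributions are also returned
for inspection.

## Numerical choices and degenerate inputs

* Quadratic fits use QR least squares; windows of ≤ 3 points are exact
  interpolations, so the final value is the last demeaned observation.
  Exactness on quadratic inputs is held to 1e−9 in the tests.
* Duration comparisons use a 1e−9 s tolerance so that `n/rate` sums at
  binary-inexact rates behave like exact arithmetic.
* A baseline window with no local maxima (or minima) leaves the
  corresponding size threshold unchanged; derivative thresholds are
  computed on the NaN-removed vector, accepting gap-spanning differences
  (flagged in the threshold history when they occur).
* Local extrema are strict; plateaus count once, at their first index.
* Zero-variance difference vectors in the t-test families produce a
  degenerate p (0 or 1) with a warning rather than an error.
* Non-monotone timestamps are dropped with a warning; empty or all-`NaN`
  streams yield empty logs.

## Problem sizes used by the shipped analyses

The packaged study (`cohort_phase_study()`, also behind
`scripts/acceptance.R`) simulates 8 subjects × 10 min at a 1000 Hz
offline rate, detects on the 60 Hz decimation, and evaluates truth at
1000 Hz — about one minute of compute. The permutation-calibration check
uses 200 replicate null datasets of 8 × 40-sample curves with full
sign-flip enumeration. Streaming/offline equivalence is asserted on ten
30 s seeded streams against an independently coded non-incremental
oracle.

## Known limitations

* The detector's accuracy on real recordings depends on device noise in
  ways the synthetic cohort only approximates; the link-jitter level is a
  single white-noise knob.
* The saccade detector and the blink-gap interpolation are simplified
  stand-ins for the cited, more elaborate routines.
* The IEI reading, though evidence-based, remains an interpretation of an
  ambiguous description; both policies are implemented and switchable.
* No hard real-time guarantees: the package processes streams as fast as
  R allows but makes no latency promises.
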