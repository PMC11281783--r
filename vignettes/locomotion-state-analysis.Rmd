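---
title: "Analysing locomotion-state coding in cortical calcium imaging"
author: "locostate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing locomotion-state coding in cortical calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locostate)
```

## The scientific question

Head-fixed mice on a spherical treadmill alternate between stillness and
locomotion bouts while visual stimuli are presented under different
visuomotor conditions (closed loop, open loop, drifting gratings,
darkness). Neuromodulatory inputs to sensory cortex — basal-forebrain
cholinergic axons in particular — are strongly locomotion-related, and the
central question this package operationalises is *what aspect* of
locomotion such a signal encodes: a graded copy of running velocity, or a
binary "moving vs not moving" state. The distinction matters because a
binary state signal is what a gating or gain-control mechanism needs,
whereas a velocity code would suggest a role in online sensorimotor
computation.

The package implements the complete analysis chain needed to ask this
question of unit × frame fluorescence recordings: drift-corrected ΔF/F,
event detection from behavior, event-triggered quantification, pairwise
correlation analyses, and nested-bootstrap inference. It pairs the chain
with a synthetic-session generator whose ground truth makes every stage
testable by parameter recovery, without any animal data.

## Data model

A `CalciumSession` extends `SummarizedExperiment`: rows are units (axons
or neurons, nested in imaging sites, nested in mice), columns are imaging
frames at one frame rate (canonically 15 Hz; 10 Hz data are resampled),
assays hold `raw` fluorescence and/or `dff`, `colData` carries the
behavior channels sampled on the imaging clock (velocity in cm/s, visual
flow, pupil, facial motion, a validity mask, the condition label), and
`metadata()` carries the condition schedule, the event table, and — for
synthetic sessions — the generator ground truth. One session holds one
behavior trace; a multi-site cohort is a list of sessions.

## The analysis chain and its parameters

All parameters sit in `analysisConfig()`; the defaults are the study's
standard values.

**ΔF/F** (`computeDFF`). The baseline is a moving 8th percentile of raw
fluorescence over a 1000-frame (≈66 s) window, truncated at the edges;
ΔF/F = (F − baseline) / median(F). The percentile window is centered by
default. For recordings dominated by monotone bleaching, a centered
window lags the decay by roughly 0.42·window/τ of F0 (≈4.5% for τ = 600 s),
while a trailing (causal) window has a bias of only percentile·window/τ
(≈0.8%); both are exposed via `align=`, and the bleach-removal validation
uses the causal mode for this reason. The rolling percentile runs in
compiled code (an incrementally maintained sorted window) and is tested
frame-for-frame against a brute-force quantile oracle.

**Resampling** (`resampleToCanonical`). Rational-ratio polyphase FIR
resampling (10 → 15 Hz is 3/2) with a Kaiser-window lowpass of 64 taps
per phase and cutoff at 0.9× the smaller Nyquist frequency; sub-4 Hz
sinusoids survive with <2% amplitude error.

**Event detection** (`detectLocomotionOnsets` and friends). A locomotion
onset is a crossing of 0.25 cm/s sustained for ≥1 s after ≥1 s below
threshold; offsets mirror this; "above" means v ≥ θ (ties go up, a choice
the source criteria leave open). Bouts pair consecutive onset/offset
events ≥4 s apart. Visual-flow onsets apply the same rule to flow speed in
open loop. Mismatch events (1-s flow halts in closed loop) are kept only
when the mouse runs uninterruptedly from −0.5 s to +1 s around the halt.
Trial state uses the same −0.5 to +1 s rule. Windows convert seconds to
frames by `round()` and are half-open. Events whose −2 to +3 s analysis
window leaves the recording are excluded at detection. The detectors are
property-tested for exact agreement with brute-force frame scanners on
randomized traces.

**Event-triggered responses** (`eventTriggeredMatrix`,
`classifyResponsive`, `onsetLatency`, `gratingLatency`). Snippets span
−2 to +3 s; the baseline window is −1 to −0.5 s (−0.5 to 0 s for
mismatch, so the locomotion response is inside the baseline); the
response window +0.5 to +1.5 s. A unit is responsive when a paired t-test
over ≥5 events separates response from baseline at p < 0.05; degenerate
zero-variance differences count as responsive when identical and nonzero,
not responsive when identically zero; units with fewer than 5 events are
excluded rather than labelled unresponsive. Latency is the first time the
across-event mean trace stays ≥2 baseline SDs above the baseline mean for
1 s (locomotion onsets, search −2 to +3 s) or 1/3 s (gratings, search 0
to +2 s); the hold must fit inside the search window, so a crossing at
+1.9 s cannot qualify for gratings.

**Velocity tuning and model comparison** (`velocityTuningCurve`,
`binarizationComparison`). Tuning bins velocity into 100 even bins over
0–6.25 cm/s and summarises each bin's per-unit means with the
hierarchical bootstrap; empty bins are undefined, never zero. The model
comparison correlates each unit's activity with velocity and with
binarized velocity over identical frames. When comparing "low" (~0.5
cm/s) with "high" (~5 cm/s) velocities across a cohort we pool ~1 cm/s
bands rather than single 1/100 bins: a single extreme bin holds only tens
of frames contributed by one or two bouts per session, and a unit-level
bootstrap cannot express that frame clustering.

**Pairwise correlations** (`buildStateMasks`,
`meanPairwiseCorrelation`, `correlationChange`,
`correlationByBaselineQuantile`). Frames are split by binarized
locomotion state and optogenetic stimulation; per-unit mean correlation
is the average Pearson correlation with every same-site unit over masked
frames; sites need ≥15 s per compared state; correlations are computed on
raw ΔF/F frames with no transition buffer (config-exposed). The
stratified analysis bins pairs by their stationary correlation and
reports the mean locomotion-minus-stationary change per quantile bin.

**Inference** (`hierarchicalBootstrapMean`, `hierarchicalPairedTest`,
`hierarchicalUnpairedTest`, `binwiseTraceComparison`,
`classicalSiteTest`). The nested bootstrap resamples imaging sites with
replacement and then units within each drawn site (each drawn site
contributing its own unit count — the source leaves this open), pooling
the drawn values into a grand mean; 10000 replicates by default, 1000 for
per-time-bin trace comparisons, which are deliberately uncorrected for
multiple comparisons and say so in their output. One-sided p values are
the proportion of replicate means on the null side of zero, ties counting
toward the null (conservative); two-sided p is twice the smaller tail.
Site-level comparisons pass a Kolmogorov–Smirnov normality gate on
z-scored values at 5% — formally a Lilliefors statistic read against the
plain KS reference, which we document rather than silently substitute —
then use t-tests or Wilcoxon tests accordingly.

## What the synthetic generator emulates

`synthConfig()`/`simulateSession()` produce sessions with the statistical
structure the analyses assume, plus full ground truth (unit coding
models, amplitudes, lags, bout table, per-state correlation targets, the
noiseless drive matrix):

* **Behavior.** A semi-Markov two-state process: stationary gaps
  (velocity jitter < 0.2 cm/s) alternate with bouts. Bout durations are
  log-normal with mean ≈40 s (clipped 5–120 s) and are coupled to peak
  velocity (coupling 0.8 on the log scale): fast runs are sustained runs.
  Within a bout, velocity starts at its peak and declines linearly so the
  last second averages (1 − `velocityDecay`) times the first (0.6 by
  default), with a per-bout log-normal decline multiplier (sdlog 0.6, so
  some bouts hold or gain speed) and slow relative noise; in-bout
  velocity is floored at 0.3 cm/s, so threshold detection and ground
  truth agree on ≥98% of frames. The long-bout choice is deliberate: with
  a 477-ms drive lag and a GCaMP6s-like kernel, the calcium of a binary
  state coder needs ~2 s to ramp after onset, and only when onset frames
  are a small share of in-bout time does the per-frame velocity-tuning of
  a state coder come out flat — the regime the study describes. Short
  bouts would make velocity a proxy for bout phase and manufacture a
  spurious high-velocity activity deficit.
* **Schedule.** Closed-loop, open-loop, grating and dark segments tile
  the session; gratings last 2–3 s with 2–4 s gray intervals and
  orientations from {0°, 45°, 90°, 270°} in either drift direction;
  1-s mismatch halts appear only in closed loop; open-loop flow replays
  the closed-loop flow.
* **Units.** `binary_state` units follow the thresholded velocity,
  shifted by the 0.477-s state lag and convolved with a causal
  double-exponential kernel (rise 0.2 s, decay 1.5 s, unit sum;
  GCaMP6s-like — the source gives no kernel); `linear_velocity` units
  follow velocity itself; `visual` units have von-Mises orientation
  tuning, additive and multiplicative locomotion gain, and a layer-5-like
  latency shortening during locomotion; `mismatch` units respond to flow
  halts; `silent` units carry noise only. A per-bout log-normal
  population gain (sd 0.3) shared across units models arousal-like
  bout-to-bout variability; it is why, across bouts, onset and offset
  responses of the population correlate more strongly for activity than
  for velocity, whose profiles vary idiosyncratically.
* **Noise and correlations.** Each unit's noise mixes a slow AR(1)
  component (coefficient 0.5 at 15 Hz) with white noise. A per-site
  latent factor with locomotion-state-dependent loading λ sets the
  within-state mean pairwise correlation to λ²; loading vectors define
  unit groups with separate factors, which is how decorrelating low-r
  pairs and hyper-correlating high-r pairs are planted for the
  stratified analysis.
* **Pupil and validity.** Pupil is a low-pass filtered locomotion state
  scaled by a condition-dependent coupling (weaker in darkness) plus a
  luminance baseline and noise; a small fraction of frames is marked
  invalid (blinks).
* **Raw fluorescence.** F = F0 · bleach(t) · (1 + ΔF/F) + offset with a
  monotone exponential bleach, so the percentile filter can be validated
  by round trip.

All randomness flows from one root seed through named substreams, so each
stage can be regenerated independently and identical configurations are
bit-identical.

What the generator does *not* emulate — and what recovery tests therefore
cannot certify on real data — includes imaging artifacts (motion, neuropil
contamination, hemodynamic signals), bursty spiking statistics and
nonlinear indicator dynamics, genuine velocity dynamics (acceleration
profiles, micro-pauses), non-locomotion arousal structure, and any
receptive-field organisation beyond single-peak orientation tuning.

## Problem sizes used in validation

The shipped validation suite runs each stage at a scale chosen to hold
Monte-Carlo error comfortably below the assertion tolerances: cohorts of
five independent single-site sessions of 40 units for the model
comparison (20-min sessions) and velocity tuning (40-min sessions, whose
sparse ~0.5 and ~5 cm/s bands need the extra occupancy); one 80-min
10-site session of 50 units each for responsive-fraction recovery;
10,000 white-noise units for the false-positive calibration of the
responsiveness test (i.i.d. noise is the appropriate null for a nominal
α; units with slow shared noise reject at ≈7% because their trials are
not exchangeable, which is a property of the data, not of the test); 200
null datasets of 10 sites × 20 units (site SD 0.5, unit SD 1) at 1000
resamples for bootstrap calibration; 1000 random traces for the
event-detector oracle. The latency-recovery cohort switches off the
locomotion response gain so that the 2-SD crossing metric measures the
planted latency shift alone, and scores the layer-5 minus layer-2/3
difference of shortenings against the same statistic computed on the
noiseless drive — the within-metric reference that cancels what the
crossing time owes to response amplitude.

## Numerical and degenerate-input choices

Percentiles interpolate between order statistics (R type 7) everywhere.
Zero-variance traces make correlations undefined (excluded from pair
means) rather than zero. A flat mean trace has no latency and warns. The
preferred orientation breaks ties toward the lower angle. Bootstrap p
values count ties at zero toward the null. `segmentBouts` skips offsets
that precede the first onset, with a message. Session serialization is
plain text (CSV + JSON at 17 significant digits), which round-trips
doubles exactly.

## Known limitations

The pupil "ceiling-effect" variability control has no stated procedure in
the source analyses and is not implemented. Hemodynamic-artifact
correction for extracellular sensors is out of scope. The package
analyses one session per behavior trace; cross-session unit matching is
the caller's responsibility (unit ids are free-form). The flat-bootstrap
equivalence and calibration results characterise the implementation on
synthetic nulls, not the statistical optimality of the hierarchical
bootstrap itself.
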