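---
title: "Methods: knee thermography, balance-board loading and inter-method agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knee thermography, balance-board loading and inter-method agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During repeated sit-to-stand exercise the skin over different knee regions
warms or cools at different rates: the region over the medial collateral
ligament (the superior-medial zone, SM) tends to warm, while the patella
(P) and patellar tendon (PT) tend to cool. Two ways of reading these
trends out of an infrared video are compared:

* **semi-automatic** -- an operator repositions a rectangular region of
  interest (ROI) on every sampled thermogram (one every 30 s over 10 min,
  20 frames) and records the ROI's maximum and minimum temperature;
* **automatic** -- a markerless keypoint tracker supplies per-frame pixel
  coordinates for twelve knee zones (six per knee) at 1 Hz, and the
  temperature is read at each tracked coordinate.

Simultaneously a four-load-cell balance board records how the body weight
is distributed: total load, per-leg shares, fore/rearfoot shares and the
centre of pressure (CoP). A participant is *asymmetric* when one leg's
mean standing share exceeds 52%. The scientific question the statistics
address is whether the two extraction methods agree (regression $R^2$,
Bland-Altman limits) and whether both identify the same relationship
between the heavier-loaded leg and the most thermally responsive leg
(AG / NAG / PAG labels).

`thermoknee` implements both extraction paths, the balance-board
processing, the agreement statistics, and -- because the underlying human
dataset is not deposited -- a synthetic-cohort generator with known ground
truth against which every stage is tested.

## The synthetic data model

### Thermal field

Each frame is a uniform baseline (default 27 °C) plus one radial blob per
zone. A blob has a **flat core** (radius 15 px) at the zone's centre
temperature and a Gaussian skirt (σ = 5 px) with compact support at
core + 4σ = 35 px. The centre amplitude follows a linear trend in time:
by default SM warms at +0.08 °C/min and P and PT cool at −0.05 °C/min,
with the other zones flat, so the frame maximum over a knee sits in the
SM region and the minimum at the patella -- the configuration both
extraction methods must reproduce. Independent Gaussian pixel noise
(default 0.04 °C, the camera's thermal sensitivity) is added per frame.

The flat core is a deliberate choice over a pure Gaussian peak. The
tracker error in the emulated system has a radial RMS of 9.3 px; on a
Gaussian peak that error multiplies the recovered amplitude (and hence the
recovered *trend*) by a random factor `exp(-r²/2σ²)` whose mean is well
below 1 for any peak narrow enough to keep neighbouring zones separated,
biasing slope recovery beyond the 10% the pipeline is required to achieve.
With a flat core wider than the typical tracker error, keypoint sampling
is first-order insensitive to tracking error while the field remains a
localized blob. The compact support additionally guarantees that a
windowed renderer and a pointwise evaluator of the same field agree bit
for bit, which is what makes the "automatic profiles equal ground truth
exactly" tests meaningful.

The generator validates that no blob's support reaches another zone's
centre (minimum pairwise centre distance > 35 px with defaults). This
both keeps the physics honest -- overlapping SM blobs from the two knees
would silently double the warming trend -- and guarantees the operator
ROIs of the two knees do not capture each other's extrema. The default
382 × 288 px geometry satisfies it comfortably; the test suite uses
288 × 160 px, a reduced size that still does.

Within one knee, P and PT (the two *cold* blobs) are placed 55 px apart,
which exceeds core + support = 50 px. This matters for the semi-automatic
method: if two negative blobs overlap, their sum between them can be
colder than either centre, the ROI minimum lands between the zones at a
grid-dependent position and acquires a sub-pixel jitter that is not linear
in time. At ≥ 50 px separation the ROI minimum provably sits on the
patella core and is exactly linear, so the noiseless end-to-end
comparison attains $R^2 = 1$ to machine precision.

### Kinematics and loading

Sit-to-stand cycles follow a raised-cosine vertical excursion (default
40 px knee travel) with per-cycle periods drawn uniformly from 3-4 s, the
metronome cadence of the emulated protocol. Phase labels: sitting below
25% of the excursion, standing above 75%, transition between; these
cutoffs give unambiguous labels on a smooth excursion. The load-cell
total follows the same excursion -- full body mass while standing
(split left/right by `left_share` and fore/rear by `rear_share`,
default 0.65 rearfoot as observed in standing), decaying to 5% of body
mass while seated (feet resting) -- so transitions are smooth and the
pre-noise corner sum always equals the instantaneous total. Per-cell
Gaussian noise defaults to 0.1 kg; the emulated board is used unfiltered,
so the pipeline applies no filtering either.

The asymmetric regime of interest is a 52-54.5% share on one leg. A
configurable `coupling_gain` (default 1 °C/min per unit excess share)
adds extra SM warming to the heavier leg, which is the mechanism the
agreement labels are meant to detect: at a 53% share it contributes
+0.03 °C/min on top of the 0.08 °C/min base trend.

### Tracker

Observed keypoints are true centres plus isotropic Gaussian error with
radial RMS 9.3 px (the emulated network's test error). Likelihoods are
drawn as `1 − Beta(1, m/(1−m))` with mean m = 0.99, the reported average
likelihood; only the mean is reported for the real system, and this is
the maximum-entropy-flavoured one-parameter choice on [0, 1] with that
mean. A configurable fraction of (frame, zone) entries (`dropout_prob`,
default 0.5%) instead gets a likelihood uniform on [0, 0.5), emulating
lost detections that the standard p-cut of 0.5 removes.

### What the generator does not emulate

No anatomy or photorealism, no radiometric camera model (emissivity,
reflected temperature, drift), no clothing or occlusion, no tracker error
correlated in time or with pose (real network error is both), and no
chair-contact force profile beyond the smooth excursion. Metal fiducial
markers can be rendered as cold spots (`render_markers = TRUE`) but are
off by default since the automatic method is marker-free; note that
rendered markers are colder than the patella and would dominate an ROI
minimum, which is realistic (operators avoid including markers in the
ROI) but is not what the bundled ROI placement does. Consequently,
passing tests demonstrate internal correctness of the algorithms and
recoverability under the stated noise model -- not performance on real
thermograms.

## Extraction rules

* **Frame sampling** targets times `k · interval` (the t = 0 frame is not
  a target), choosing the nearest acquired frame, ties to the earlier
  frame. A 600 s run therefore yields exactly 20 frames at 30 s and 600
  at 1 s, matching the emulated protocol's counts.
* **ROI extrema** scan the rectangle clipped to the frame; ties break to
  the row-major first occurrence. Positions are reported in full-frame
  0-based coordinates, origin top-left, y down.
* **Keypoint sampling** rounds coordinates half-up to pixel centres and
  averages a `(2r+1)²` window (default r = 1 to damp single-pixel noise;
  r = 0 for exactness tests -- the real system's footprint is not
  documented, so both are supported). Entries below the p-cut are
  omitted, not interpolated; interpolation happens only when the two
  methods are aligned for comparison, which is where the emulated
  analysis states it.
* **Smoothing** is robust lowess: a window of `max(2, ceil(span · n))`
  nearest points (default span 2%), tricube distance weights, local
  linear fit, then up to five bisquare reweighting passes with robustness
  weights `(1 − min(|r|/6·MAD, 1)²)²`. Two numerical details:
  iteration stops early when the fit is tight everywhere (within
  10⁻⁹ of the data scale), which makes an exactly linear series pass
  through unchanged; and when every point in a window has been flagged
  as an outlier (a spike's own neighbourhood), the fit falls back to the
  nearest clean points, which is what removes an isolated spike
  completely rather than leaving the first-pass remnant. Smoothing is
  idempotent in its target regime (trend plus isolated spikes); on
  broadband noise a second pass keeps shrinking residual variance, as
  for any local-linear smoother, so the pipeline smooths exactly once,
  and only for slope-based leg matching (regressions use raw profiles,
  since whether the emulated analysis regressed smoothed or raw data is
  unstated and raw is the conservative choice).

## Balance-board processing

The static weight is the median of the total load over samples above its
75th percentile -- robust to the proportion of time spent seated.
Standing/sitting thresholds default to 80%/25% of static weight; the
emulated protocol describes the phases only qualitatively, so both are
exposed as parameters. Cycle counting collapses the definite phases and
counts sitting→standing transitions. CoP uses the standard corner-moment
formula with the published 433 × 238 mm sensor spans (share computations
are span-independent). The asymmetry flag compares the **mean** standing
share against a strict 52% threshold; the per-sample maximum is also
reported, since whether the emulated 52% refers to mean or peak is
unstated and the mean is the participant-level quantity.

## Agreement statistics

The four regional comparisons are ligament (semi-automatic maximum vs
automatic SM) and patella (minimum vs P), per leg. The automatic series
is linearly interpolated onto the semi-automatic grid with no edge
extrapolation. $R^2$ comes from OLS of the automatic on the
semi-automatic values; a comparison is "strong" at $R^2 \ge 0.5$ (the
threshold is not printed for the emulated analysis; 0.5 cleanly separates
its reported strong and weak clusters and is configurable). Bland-Altman
limits are bias ± 1.96 sd with the n−1 sd and no repeated-measures
correction, the classic construction. "Most thermally responsive leg" is
operationalized as the OLS slope of the zone profile in °C/min (larger
slope for heating, more negative for cooling); slopes within
10⁻⁶ °C/min are an indeterminate tie and are excluded. Labels: both
methods matching the heavier leg → AG, neither → NAG (alias DAG),
exactly one → PAG. BMI stratification defaults to the 25 kg/m²
normal/overweight boundary; the 18.4 figure that appears in the emulated
description conflicts with standard BMI bands and is available via
`bmi_cutoff` for strict emulation.

## Problem sizes and determinism

Unit and property tests run the generator at 288 × 160 px and 1-2 min
durations; the end-to-end and replicate tests use the full 600 s
protocol at 288 × 160 px, and the acceptance script runs a 20-participant
cohort at the native 382 × 288 px. These sizes were chosen so the full
suite exercises every code path at the study's sampling design while
remaining comfortable to run repeatedly during development. All
randomness flows from a single integer seed through fixed per-component
sub-seeds (kinematics, tracker, load cells, per-frame pixel noise), so a
config is reproducible to the byte, including lazily rendered frames
accessed in any order.

## Known limitations

* The synthetic thermal field is stylized (flat-core blobs on a uniform
  baseline); absolute $R^2$ or RMSE values from synthetic cohorts
  characterize the generator's noise model, not real thermograms.
* Tracker error is i.i.d. across frames; real pose-estimation error is
  autocorrelated and pose-dependent, so real-data dropout and error
  bursts are harsher than the model.
* Semi-automatic extraction in the bundled pipeline positions ROIs from
  ground-truth knee motion; with real data the ROI track must come from
  an operator annotation file (`track_roi` applies externally supplied
  displacements).
* At zero noise the two methods see identical fields, so PAG labels can
  only arise under noise; the zero-noise cohort check therefore
  exercises AG/NAG only.
* Balanced participants have near-tied slopes between legs; their
  heating/cooling matches are noise-driven, which is the correct
  no-signal behaviour (match rates near 50%) rather than a defect.
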