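---
title: "Methods: how pupilprep cleans, fuses and synchronizes pupil data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how pupilprep cleans, fuses and synchronizes pupil data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilprep)
```

## The problem

A video-based eye tracker reports each eye's pupil diameter at a nominal
120 Hz; a facial-expression channel derived from webcam video runs at
30 Hz.  A multimodal acquisition platform exports both into one wide CSV
where every row belongs to one modality's own clock, so the table is a
ragged interleaving of pupil-only and facial-only rows.  Before any
analysis of pupillary dynamics can be trusted, the pupil channel must be
stripped of blink and occlusion artifacts, reconstructed on a common time
base, fused across eyes, expressed relative to a baseline, and re-aligned
with the facial stream.  `pupilprep` implements that sequence as
composable stages with a one-call orchestrator, `run_pipeline()`.

Each eye is processed independently up to the fusion stage.  This matters
because artifact filtering is destructive: if the eyes were filtered
jointly, a monocular tracking loss would delete the other eye's valid
samples.

## Stage-by-stage model and assumptions

### Cleaning

Null rows and exact duplicate timestamps (export glitches) are dropped —
the first occurrence of a duplicated timestamp survives, a deterministic
choice.  Diameters outside **2–8 mm** (inclusive) are physically
implausible for adult pupils and are removed; the bounds are parameters
(`min_mm`, `max_mm`) because clinical or infant populations differ.
Inclusive bounds follow from reading the rule as "remove what lies
*outside* the range": a value exactly at 2 mm is inside.

### Global outliers: dilation speed + MAD

The normalized dilation speed of sample $i$ is the larger of its backward
and forward absolute difference quotients (mm/ms).  Dividing by the
actual time step means a jump across a data gap is judged by its *rate*,
not its size.  At the trace ends only one neighbour exists; the one-sided
quotient is used there rather than discarding the endpoints.

The removal threshold is $\mathrm{median}(d') + n\,\mathrm{MAD}(d')$ with
$n = 20$.  The MAD here is the *raw* median absolute deviation, without
the 1.4826 normal-consistency constant — the defining formula has no such
constant, and the multiplier $n$ absorbs the scale.  (`mad_raw()` is
deliberately distinct from `stats::mad()`; a test pins down the 1.4826
relation between them.)  Removal is strict (`>`) and single-pass:
recomputing the threshold after each removal round is available as
`iterate = TRUE` but off by default, since a single application is the
documented procedure.  The detector assumes roughly consistent dilation
speeds across the recording; genuinely fast physiological events could in
principle be clipped, which is the price of a global robust threshold.

### Local outliers: moving-average deviation

A global threshold misses brief excursions that are only anomalous
relative to their neighbourhood — the signature of partial eyelid
occlusion, where the tracker still reports a value but underestimates the
diameter for a frame.  The local pass computes a **trailing** moving
average over $k = 23$ samples (the printed form of the definition is
trailing; `align = "centered"` implements the alternative reading and is
available as a flag), with a shrinking warm-up window over the first
$k-1$ positions so the deviation series has full length.  Samples whose
absolute deviation from the moving average exceeds
$n \cdot \mathrm{median}(\delta)$ with $n = 18$ are removed; the moving
average is computed once on the stage's input, not recomputed during
removal.

The window should span roughly one blink.  At 120 Hz (8.33 ms/frame) and
blink durations of 150–400 ms, windows of 18–48 samples qualify; 23 is
the default, and `remove_local_outliers()` warns when
`window_k × frame period` leaves the 150–400 ms span.

### Upsampling: shape-preserving PCHIP

The cleaned trace is reconstructed on a 1 ms grid (1000 Hz) with the
piecewise cubic Hermite interpolant using Fritsch–Carlson monotone
derivative estimates (weighted harmonic mean of adjacent secant slopes;
zero at local extrema; clamped three-point estimates at the ends).  Two
properties make this the right interpolant for pupil data: on any
monotone run of knots the interpolant is monotone, and it never
overshoots local extrema — a cubic spline would ring around the steep
edges that remain after artifact removal, fabricating diameters the eye
never had.  The millisecond grid is anchored at integer milliseconds
(`ceiling(t_first)`), which makes grids from different eyes — and
different recordings — commensurable, so later joins are exact integer
matches.  No extrapolation is performed: values outside the observed span
cannot be validated.

Reconstruction across a long dropout is fabrication regardless of method,
so interpolated points bridging an original inter-sample gap **strictly
greater than 250 ms** are masked out afterwards; points coinciding with
real observations always survive.  A gap of exactly 250 ms is bridged.

`compare_interpolators()` quantifies method quality by randomly holding
out a fraction of interior samples (seeded), refitting on the rest, and
scoring RMSE and maximum absolute error at the held-out times.  The
holdout design (fraction, uniform interior draw) is this package's own
validation protocol.  On smooth synthetic traces PCHIP attains lower mean
RMSE than linear interpolation; the comparison uses noise-free traces
because interpolation *bias* is the quantity of interest and additive
tracker noise would put an identical irreducible floor under every
method.

### Binocular fusion

The two millisecond grids are combined by a full outer join on exact
timestamps.  Where only one eye has a value, the other is imputed by
ordinary least squares fitted on the co-observed rows — two directional
fits (right-from-left and left-from-right), because the prediction
direction depends on which eye is missing.  The model is fitted per
recording: anisocoria is individual, so coefficients must never be
pooled across participants.  A warning fires below 30 co-observed rows;
fewer than 2, or zero predictor variance, is an error.  Imputation never
overwrites an observation, and rows missing both eyes are kept (as
missing) so the time base survives later joins.  The mean diameter is
the arithmetic mean of left and right wherever both are present.

### Baseline and normalization

The baseline window is the earliest stretch of the **raw** (cleaned,
pre-interpolation) binocular data in which both eyes are valid at every
sample, successive samples are at most 12.5 ms apart (1.5 × the nominal
frame period — tolerant of jitter, intolerant of dropped-frame runs; the
definition of "consecutive" is numerically open, so the tolerance is a
parameter), and the stretch spans at least 400 ms.  Locating the window
on raw data prevents interpolation from papering over gaps when deciding
*where* the baseline is; the baseline *value* is then the mean of the
processed mean-pupil series over that window, and is computed from the
fused mean series rather than per eye because the normalization consumes
a single diameter.  If no qualifying stretch exists the pipeline stops
with an explicit error — a recording that never shows 400 ms of clean
binocular data has no defensible baseline.

The normalized series is $(d - b)/b$: dimensionless, 0 at baseline,
invertible back to millimetres as $b(1 + x)$.  Its mean over non-missing
samples is the recording-level summary `mean_normalized_dilation`.

### Integration with the facial stream

The millisecond pupil table is reduced to the facial rate by averaging
within half-open 33 ms bins anchored at the first pupil timestamp, each
bin labelled by its start time; with a gapless 1000 Hz input every full
bin holds exactly 33 samples.  33 ms is used as stated rather than the
exact 33.33 ms period of 30 Hz; the exact-rate alternative is available
via `bin_width_ms = 1000/30` for drift-free binning over long
recordings.  Facial timestamps are rounded to the millisecond
(half-away-from-zero; ties introduced by rounding are averaged rather
than dropped) and the two tables are merged by a full outer join on
exact timestamps — facial rows are *not* snapped to pupil bin edges, so
the output keeps the union time base with explicit missingness.  Facial
metrics are never interpolated: muscle-derived expression metrics have
no meaningful between-frame values.

## The synthetic recording generator

`generate_recording()` emulates the raw export so every stage can be
validated against labelled ground truth without any participant data.
The clean signal is a baseline (default 4 mm) plus a slow hippus-like
oscillation (0.1 mm at 0.2 Hz) plus raised-cosine evoked dilation events
(0.2–0.6 mm over 1–3 s, ~4/min) — any smooth C¹ pulse suffices to
exercise interpolation and the outlier passes, so no physiological
light-reflex model is attempted.  The right eye is an affine function of
the left (slope 0.9, intercept 0.3) plus coupling noise, modelling stable
anisocoria.  Per-sample tracker noise (0.02 mm, typical of video
eye trackers) is added to both eyes; without it the robust MAD/MA
thresholds would degenerate toward zero on an implausibly noise-free
signal.

Artifacts mirror what trackers actually produce, each labelled in the
ground truth: **blinks** (12/min, 150–400 ms, both eyes together) with
two fast in-range closing-edge samples, a missing closure span, and two
reopening samples — the edges (`blink_step`) are what the dilation-speed
pass must catch, the closure is caught by null filtering; **occlusion
spikes** (6/min/eye), single-sample apparent constrictions of 0.4–0.9 mm
— large because partial lid coverage biases the fitted pupil ellipse
substantially; **out-of-range values** (4/min/eye) far outside 2–8 mm;
and **duplicated rows** (0.5 %).  The first 2 s are kept free of evoked
events so a baseline window exists.  All defaults were fixed from these
field-typical magnitudes; they are the package's standing test
conditions, not tuning knobs.

What the generator does *not* emulate — pupil foreshortening with gaze
angle, luminance responses, slow drift of tracker calibration, correlated
(non-white) measurement noise — bounds what passing tests show: they
certify the algorithms against the artifact classes modelled here, not
performance on every real-world pathology.

On these conditions the measured stage-level recovery (20 replicates of
5-minute recordings) is: the dilation-speed pass removes essentially all
blink-edge artifacts, the moving-average pass removes >90 % of occlusion
spikes, and the two passes jointly remove ~0.5 % of clean samples.  One
subtlety: with the standard multipliers the global pass alone already
catches most large occlusion spikes before the local pass sees them, so
spike recovery is attributed to the local detector by applying it
directly to the cleaned trace — the measurement isolates each detector on
the artifact class it exists for, while the clean-sample loss is measured
in true pipeline order.

```{r example}
rec <- generate_recording(synthetic_spec(duration_s = 30, seed = 1))
res <- run_pipeline(rec$table)
res$baseline
head(res$merged[res$merged$has_pupil & res$merged$has_facial, ])
```

## Numerical choices and degenerate inputs

* Timestamps are milliseconds (double) everywhere; rounding is
  half-away-from-zero, so behaviour at .5 ties does not depend on IEEE
  round-to-even.
* Strict inequalities at both outlier thresholds and at the gap limit:
  "exceeds" means `>`.  A constant trace therefore loses nothing to the
  local pass even though its threshold is 0.
* Outlier detectors are subset operations — surviving samples are
  bit-identical to their inputs; tests enforce this.
* Two knots degrade PCHIP to the secant line; fewer than two is an
  error, as is any query outside the knot span.
* Thresholds are monotone in their multipliers: raising `n` never
  removes more (tested property), so sensitivity analyses move in the
  expected direction.
* Traces shorter than 2 samples cannot support a speed metric and error
  out with a clear message; an empty recording aborts the pipeline at
  the split stage with the stage named.

## Problem sizes used in validation

The shipped validation suite runs on synthetic material sized for quick,
deterministic feedback while still exercising every code path at
realistic rates: oracle-equivalence checks on 100 random traces of up to
2,000 samples, PCHIP fidelity on 1,000 random knot sets, artifact
recovery on 20 replicates of 5-minute binocular recordings (~36,000
samples per eye each), regression recovery at n = 5,000, and end-to-end
runs of 30–120 s.  These sizes are the package's validation design;
nothing in the implementation depends on them.

## Known limitations

* The baseline is an early clean stretch of the recording, not a
  controlled pre-task measurement; if the participant was already
  aroused at recording start, normalized dilations are biased low.
* Linear cross-eye imputation assumes a stable affine binocular
  relation; rapid asymmetric dynamics would be reconstructed poorly.
* The MAD detector assumes stationary dilation-speed scale; adaptive or
  learned thresholds are out of scope.
* Only the five shipped interpolants are available; modified-Akima and
  learning-based imputation are not implemented.
* Facial metrics are consumed, never computed or interpolated.
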