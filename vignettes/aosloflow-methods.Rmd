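---
title: "Methods: quantifying immune-cell dynamics and single-vessel flow in label-free retinal video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying immune-cell dynamics and single-vessel flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aosloflow)
```

## What this package computes

Adaptive-optics scanning-light ophthalmoscopy (AOSLO) with a phase-contrast
detection geometry renders translucent immune cells visible in the living
retina with near-infrared light alone, and a fast line-scan mode across a
single vessel records every passing blood cell. From such recordings two
complementary physiologies are quantified at once:

* **Immune-cell dynamics** — per-frame cell detection on temporally averaged
  video, cell counts and densities (cells/mm²), nearest-neighbour track
  linking, and the motility metrics *displacement over 100 s* and
  *confinement ratio* (displacement divided by path length; 1 for ballistic
  motion, towards 0 for confined wandering).
* **Single-vessel hemodynamics** — red-blood-cell velocity from the slope of
  cell streaks in the space–time (kymograph) image, inner lumen diameter from
  the full width at half maximum (FWHM) of a motion-contrast profile, and the
  volumetric flow `Q = k * (pi/4) * D^2 * V` in nL/s. Longitudinally, relative
  changes of `V`, `D`, `Q`, the arteriole–venule flow-conservation regression
  and the `V/D^2` decomposition separate velocity-driven from
  diameter-driven flow changes.

Everything is exercised end to end on a synthetic video generator with exact
ground truth, so each stage's recovery error is measurable without instrument
data.

## The synthetic scene and what it does (and does not) emulate

`simulation_config()` / `simulate_cell_video()` build a calibrated field:
`um_per_px = field_size_deg * 34 / ncol` (2–5° of visual angle span 68–170 µm
of retina). The scene contains:

* **Cells** as radial difference-of-Gaussians profiles (dark core, bright
  annulus, nominal 13 µm diameter) — the qualitative phase-contrast
  appearance. Initial placement is hard-core (centres at least one diameter
  apart, one diameter from the field edge): rendered cells are solid bodies
  and may not interpenetrate or begin clipped by the field stop. Motion is
  stationary, constant drift, or a per-frame Gaussian random walk, with
  positions clamped (not wrapped) at the field edges.
* **Background** as band-limited noise texture (Gaussian correlation length
  8 µm, SD 6 intensity units against a cell contrast of 40) standing in for
  out-of-focus retinal backscatter. The correlation length is specified in
  micrometres so the same physical scene is produced at any pixel scale; it
  is deliberately coarser than a cell so that in-focus cells and defocused
  background occupy overlapping but distinguishable scales, as in the
  instrument.
* **Instrument effects**: integer-rounded Gaussian inter-frame translation
  (residual eye motion under anesthesia — pure translation, no rotation or
  shear), sinusoidal fast-axis resampling (resonant-scanner distortion,
  `x = (1-a)u + a(1-cos(pi u))/2`), and additive Gaussian sensor noise.
  Eye motion is applied by cropping a padded canvas, so shifted frames carry
  no border artefacts, and the ground truth stores sub-pixel cell centres
  *before* eye motion together with the true shifts.

`simulate_vessel_kymograph()` renders the line-scan geometry: rows are
position along the scanned line, one column per line period (15 kHz), a
bright lumen band of known width, and Gaussian cell streaks advected by the
pulsatile velocity `v(t) = V0 (1 + m sin(2 pi f_c t))` (mouse cardiac
frequency 6 Hz by default). Poisson entry times populate the band; at
`V0 = 0` streaks are given an exponential dwell (mean 20 ms) because a cell
that never moves along the line is physically a cell drifting through the
thin scan plane, and a truly static streak is indistinguishable from the
lumen background. The resolvability precondition is streak-width based: a
cell must advance less than about two streak widths per line period.

What the generator does **not** emulate: fluorescence channels, leukocyte
rolling or transendothelial-migration morphology, pseudopod remodeling,
line-by-line temporal skew within a frame, and intensity nonuniformity.
Passing recovery tests on this scene therefore demonstrates correctness of
the measurement chain under idealised appearance, not robustness to every
property of in vivo data.

## Registration and averaging

Shift estimation is whole-frame FFT cross-correlation with parabolic
sub-pixel refinement; integer shifts of a textured scene are recovered
exactly. The registration reference defaults to the median-sharpness frame
of the first second (robust to transient opacity). Applied shifts are
integer; vacated pixels become `NA` sentinels that temporal averaging
excludes from its means — zero-filling would darken the field edges and
bias detection.

One failure mode matters for motility work: when bright *moving* cells
contribute correlation energy comparable to the static background, the
correlation peak is dragged along with them, producing a slow common-mode
position drift that corrupts displacement measurements far below the pixel
scale. The cure implemented here is the standard two-pass moving-object
masking: register once, detect cells, map the detections back to raw-frame
coordinates (`raw_exclusion_disks()`), and re-estimate shifts with the cell
disks replaced by a static-background estimate (`static_background()`, the
pixelwise temporal median of the first-pass registration) — the estimation
frames then contain no moving structure, while the *applied* frames are
untouched. A flat median fill is deliberately not used: a uniform disk
moving with the cell is itself a correlated blob and still drags the peak
by a fraction of a pixel.

`temporal_average()` implements both averaging styles used on this data:
non-overlapping 5-frame averages (stride = window) as detection
pre-processing — 25 averaged frames of a 25 Hz recording span 5 s, which
reconciles the counting rule below with the native frame rate — and
running 25–50-frame averages (stride 1) for time-lapse display. Output
frame count is exactly `floor((n - window)/stride) + 1` and timestamps are
window centres.

## Detection

Two detectors satisfy one contract (frame in, probability map in [0, 1]
out), so the downstream pipeline is detector-agnostic:

* the **learned** detector is a ridge regression from a bank of zero-mean
  convolutional features (matched filter for the cell profile, two
  difference-of-Gaussians bands, smoothed gradient magnitude, and a
  texture-band channel at 1.5–4 cell radii that lets the fit subtract the
  local background estimate) onto unit-peak Gaussian label maps
  (`make_label_map()`, sigma = half the cell radius). The fit is closed
  form — identical data give identical weights — and a calibration maps the
  lower quartile of predicted values at label peaks to probability 1.
* the **classical** detector is a matched filter followed by
  centre-surround background subtraction, normalised by the response to an
  ideal rendered cell of the configured contrast. It needs no training and
  cross-validates the learned model.

Both detectors divide their response by `sensitivity` (default 0.75) before
clipping, so a cell at 75% of nominal contrast still saturates: this keeps
the fixed `>= 0.90` probability threshold — the operating point used for
cell counting — from discarding slightly dim cells. Zero-mean filters make
both detectors invariant to additive intensity offsets.

`detect_centroids()` binarises at the threshold, labels 8-connected
components, drops components below `min_area_px` (default 3 px: with
unit-peak Gaussian heat maps the suprathreshold core of a true cell is only
a few pixels, so a large area gate would reject real cells — the gate is
only meant to kill isolated noise pixels), and reports intensity-weighted
centroids. Each detection is then re-localised two ways: a least-squares
2-D quadratic fit on the *unclipped* response surface (the saturated
probability plateau destroys sub-pixel shape), and optionally
(`detect_stack(refine = "profile")`, the default) a model-based fit of
`plane + cell profile` in image space. Within a window of about one cell
radius the 8 µm-correlated background is close to planar, so the plane term
absorbs most of the texture-gradient bias that limits centroid accuracy —
the dominant error source for slow-cell displacement.

The cell count of a video is the mean number of detections over the first
25 averaged frames (5 s); density divides by the field area in mm².

## Tracking and motility

`link_detections()` is greedy mutual-nearest-neighbour linking within
13 µm (one cell diameter per 0.2 s averaged frame — immune cells move far
less), distance-sorted with ties resolved toward the lower cell id for
determinism, with an optional gap tolerance for transient detection
dropouts. `qc_tracks()` automates the visual rejection of mislinked traces:
a track is flagged when any single step exceeds `jump_factor` (default 5)
times the track's reference step, where the reference step is the median
step floored at `min_step_um` (default 1 µm, about one pixel of centroid
noise). The floor matters: for cells moving below localisation noise the
median step is essentially zero and a pure ratio rule would flag every slow
cell; with the floor, the rule still catches jumps at the adjacent-cell
scale (>= 5 µm) it is meant to reject.

`displacement()` is the distance between the sample nearest the track start
and the sample nearest 100 s later; `confinement_ratio()` divides by the
path length over the same window and is reported as `NA` (undefined), not
zero, for a cell that never moved. `normalize_traces()` recentres tracks on
their origin for rose plots against the 13 µm typical-cell-radius circle.

## Velocimetry, diametry, flow

Streak-slope estimation uses shifted-column cross-correlation: within each
analysis window (default 50 ms) the correlation between columns `delta`
line-periods apart peaks at a row shift of `slope * delta`. A first pass at
`delta = 1` brackets the slope; a second pass enlarges the lag for
precision — bounded by the streak traversal time, and halved adaptively if
the correlation collapses (nearly static streaks live shorter than the
traversal bound suggests) — and refines the peak with a least-squares
quadratic over ±3 samples, which is stable on broad noise-flattened peaks
where a 3-point parabola is not. A sheared-projection (Radon-style)
variance objective was evaluated first and rejected: on finite streak
segments confined to the lumen band its maximum sits several percent away
from the true slope, outside this package's own recovery targets, whereas
the cross-correlation estimator is unbiased to within ~0.5% across
2–40 mm/s. Featureless windows (normalised peak correlation below 0.05)
return `NA`, never 0 — zeros would bias cycle averages.

`cycle_average_velocity()` averages over the largest whole number of
cardiac cycles, cancelling the pulsatile modulation exactly in the ideal
case. `build_motion_contrast()` maps per-pixel temporal SD over temporal
mean (gain-invariant; flowing blood bright, static tissue dark), and
`measure_diameter()` takes the FWHM of motion-contrast profiles sampled
perpendicular to the weighted principal axis of the suprathreshold mask —
handling vessel orientation — at quarter-pixel steps with sub-pixel
half-max crossings. `compute_flow()` applies `Q = k (pi/4) D^2 V`; the
profile factor `k` (centreline-to-mean velocity correction) defaults to 1
and cancels in all relative-change analyses.

## Longitudinal analysis

`longitudinal_changes()` computes percent changes of `V`, `D`, `Q` and
`V/D²` per vessel against its own baseline; `flow_conservation_fit()`
regresses venule on arteriole flow changes (conservation of flow through a
closed bed predicts correlated changes); `summarize_cohort()` reports
mean ± sample SD with n per timepoint; a Friedman test across timepoints is
delegated to `stats::friedman.test()`. The conserved-cohort generator draws
a shared true flow change per replicate and timepoint (cohort-level
inflammation-like time course: 0, +30, +67, +20, +5 percent, 25-point
between-replicate SD) and adds 5% multiplicative measurement noise to each
vessel independently.

## Numerical choices and degenerate inputs

* Seeds are mandatory in every generator config; identical configs are
  bit-identical, and `run_pipeline()` reports are byte-identical for a
  fixed seed.
* Stage flags on `video_stack` move only forward
  (raw → desinusoided → registered → averaged); desinusoiding is not an
  involution, and the flag prevents double correction.
* Zero-variance frames cannot be registered (error, not a silent 0);
  blank kymograph windows and zero-path-length confinement ratios are
  undefined (`NA`), not zero.
* The de-sinusoid inverse is evaluated on a 10x oversampled grid; the
  distort-then-correct residual on smooth patterns stays below 0.5
  intensity units.
* Tie-breaks in linking go to the lower cell id; component labelling is
  flood-fill 8-connected.

## Problem sizes

The shipped tests and the acceptance script run the studies at desk scale
chosen to keep every recovery band measurable: 200-frame registration
fields; 20 training / 15–20 held-out frames of 128² px with 5 cells for
detector scoring; a 2510-frame, 256² px (0.66 µm/px — within the
instrument's native sampling range) drift recording for the 100 s
displacement study; 600-cell truth-level random-walk cohorts; 0.4–0.6 s
kymographs at 15 kHz; and 100-seed conserved cohorts of 6 replicates by
5 timepoints.

## Known limitations

* The appearance model is idealised; contrast heterogeneity, shape change
  and pseudopod dynamics of real immune cells are not simulated, so
  detector scores here are upper bounds on real-data performance.
* Registration is whole-frame translation only — appropriate for an
  anesthetized mouse, not for awake human eye motion (saccades, drift,
  intra-frame distortion).
* The tracker is frame-to-frame greedy: no global optimisation across
  gaps, no merge/split handling.
* Absolute flow carries the profile factor `k` as a configurable
  assumption; only relative changes are `k`-free.
* The diameter measurement assumes a single straight-ish vessel in the
  field; branching vessels need cropping first.
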