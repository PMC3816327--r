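---
title: "Decoding face categories from retinotopic V1 subregions: models and methods"
author: "v1facedecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding face categories from retinotopic V1 subregions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v1facedecode)
```

## The scientific problem

Primary visual cortex (V1) is retinotopically organized: distinct parts of
the visual field — say, the eyes and the mouth of a centrally fixated face —
project to distinct cortical patches. If higher-order face processing feeds
back into V1 in a task-dependent way, then the multivoxel activity pattern
of those patches (and of the rest of V1) should carry decodable information
about face category (expression, gender) that varies with the task the
observer performs (expression vs. gender categorization).

Testing this requires a long analysis chain: an event-related design with
interleaved face and feature-mapping trials, retinotopic mapping,
hemodynamic modelling, definition of eye/mouth/rest-of-V1 patches, and
cross-validated pattern classification. `v1facedecode` implements that
chain as a reusable, fully tested pipeline. Because no subject data are
available, the package pairs every analysis stage with a synthetic forward
model that generates BOLD data with known ground truth, so each stage can
be validated by parameter recovery and null calibration rather than by
re-analysis of an existing dataset.

## The forward model (what the generator emulates)

A simulated experiment consists of:

* **Design** — six runs, 720 trials (120 per condition) over six
  conditions: happy, fearful and neutral faces, eye- and mouth-mapping
  checkerboards, and a fixation baseline. Each trial is a 1 s stimulus
  followed by 3 s fixation (4 s SOA) at TR = 1 s, randomly ordered within
  run; the task alternates across runs between expression and gender
  categorization. Runs get a configurable lead-in/out of 10 volumes each;
  only SOA and trial counts are constrained by the protocol, so the exact
  run length is a package choice. Face trials carry a balanced male/female
  stimulus attribute.
* **Voxels** — a ground-truth region partition (eye, mouth, rest-of-V1,
  outside-V1) with a preferred polar angle per voxel. This partition
  stands in for the manual, surface-based delineation that real analyses
  perform; the pipeline's only use of ground truth outside the generator
  is the V1 mask handed to the patch-definition stage.
* **Responses** — an amplitude map over (condition, task, voxel). Faces
  drive all V1 voxels at a base amplitude (the face covers the mapped
  field); each mapping checkerboard drives only its own region, which is
  what makes the eye-minus-mouth localizer contrast informative; baseline
  drives nothing. Class-discriminative signal is *opt-in*: a planted
  pattern adds `delta * z_v` (voxel-wise standard normal `z`) to one
  condition in one region, optionally per task. A truth with no planted
  rows is exactly null: identical amplitudes across the to-be-decoded
  classes.
* **Noise** — white Gaussian noise (optionally AR(1), coefficient 0 by
  default since the autocorrelation of the data is unknown) plus a linear
  drift per volume. With the defaults (base amplitude 1, planted deltas
  around 0.5, sigma 1) the contrast-to-noise ratio of a planted signal is
  about 0.5. Every random draw is a deterministic function of a seed;
  sub-seeds for runs, subjects, folds and draws are derived from one
  master seed, so whole reports reproduce bit-identically.
* **Wedge runs** — for retinotopy, each responsive voxel emits the
  periodic steady-state response of a rotating wedge: the HRF-convolved
  reference for the first 45° sector, circularly delayed in proportion to
  the voxel's preferred angle. The steady-state (circular) convolution is
  a deliberate choice: the stimulus is periodic, and it makes circular
  reference shifts correspond exactly to angle rotations.
* **Gaze** — fixation jitter plus square-pulse excursions, the fixture
  for the saccade rule. The sampling rate defaults to 60 Hz (the real
  eyetracker rate is unknown), so a 150 ms saccade spans ≥ 9 samples.

What the generator does **not** emulate: spatial structure (voxels are
exchangeable within a region), scanner artefacts (spikes, motion),
physiological noise spectra, and hemodynamic nonlinearity. Passing tests
therefore demonstrate correctness of the analysis code under the stated
model, not robustness to every property of real data.

## Analysis stages

### Preprocessing

Per run and voxel: linear-trend removal (least-squares line removed, mean
re-added) followed by temporal high-pass filtering at 0.006 Hz. The filter
is implemented as regression on sine/cosine harmonic pairs at every run
frequency below the cutoff — exactly linear, phase-free and
mean-preserving. Harmonic *pairs* rather than a single-phase cosine set
are used because one phase per frequency cannot null a slow sinusoid of
arbitrary phase; with pairs, any on-grid component below the cutoff is
removed exactly and components at ≥ 5× the cutoff pass within 1%.

### Hemodynamic modelling

* `double_gamma_hrf()` — difference of two gamma densities
  (peak delay 6 s, undershoot delay 16 s, unit dispersions,
  peak:undershoot ratio 6, 32 s support), peak-normalized. The exact
  "standard two-gamma" constants are not prescribed anywhere, so no
  result depends on them — recovery tests only require the same kernel in
  forward and inverse direction.
* `build_fir_design()` — deconvolution design: one stick predictor per
  condition and post-stimulus bin (default 20 bins of one TR, i.e. 20
  predictors per condition, baseline excluded) plus a mean confound.
  At a fixed 4 s SOA the stick columns of bins 4 apart are nearly
  collinear except at run edges; at very small trial counts the design
  can become numerically rank-deficient, in which case the fit falls back
  to the minimum-norm pseudo-inverse with a warning.
* `build_single_trial_design()` — beta-series estimation: one
  HRF-convolved boxcar column per trial plus a mean confound; OLS betas
  are the trial patterns for decoding.
* `fit_ols()` / `t_contrast()` — plain least squares (no prewhitening),
  residual variance RSS/(volumes − rank), classical contrast t with the
  fit's dof.
* `peak_and_window()` — summaries of deconvolved time courses: the value
  at the bin in 5–7 s where the *grand-mean* response peaks (choosing the
  peak on the grand mean avoids biasing condition comparisons), and the
  mean over 3–9 s inclusive.
* `fixed_effects_design()` — concatenated analysis with one predictor per
  condition and one intercept confound per (subject, run) block.

### Retinotopy

`phase_map()` correlates every voxel with the predicted response for the
first 1/8 stimulation cycle (32-volume cycles, 4 active volumes),
circularly shifted in steps of 4 volumes = 45°; the best shift gives the
polar angle. Shifts are circular because the stimulus is periodic. The
mapping significance threshold is not prescribed; the default flags
voxels with best r < 0.25 as sub-threshold, and zero-variance voxels get
r = 0. Field-sign-based area borders are out of scope — the synthetic
region truth provides the V1 mask.

### Patch definition

The eye-minus-mouth contrast t map is split at a symmetric threshold
(default 3.2): t ≥ +3.2 → eye patch, t ≤ −3.2 → mouth patch (disjoint by
construction). The per-subject manual threshold adjustment used in
practice is subjective, so the package keeps one configurable threshold.
Rest-of-V1 is the V1 mask minus the patches *dilated* by re-thresholding
at a lowered value (default 1.5 — the real lowered value is never stated,
so it is configurable), intersected with the responsive-voxel map
(all-faces-vs-baseline, P < 0.0001 Bonferroni-corrected by default; the
correction used originally is unnamed). `fdr_threshold()` provides the
Benjamini–Hochberg step-up rule (q = 0.01) used for map thresholding.

### Decoding

`loro_cv()` implements leave-one-run-out cross-validation with a strict
leakage contract: folds are defined by run membership, and the per-feature
min/max/range normalization to [−1, 1] is fitted on training rows only and
applied unchanged to the test fold (test values may leave the range;
constant features map to 0 so the transform is total). The classifier is
a linear soft-margin SVM with C = 1 (libsvm via e1071, no internal
rescaling); multi-class problems use one-vs-one voting with libsvm's
default tie handling. Test patterns are scored per trial
(`single_trial`) or as the per-class mean raw test pattern
(`averaged`) — averaging precedes normalization because the mean pattern
is formed in beta space. To equate feature counts across regions,
`subsample_schedule()` yields 15 strictly increasing set sizes from 1 to
160 (the enumerated sequence `1:10:160` lists 16 values while the stated
count is 15; the package honors the count and the end points, keeping the
raw arithmetic sequence behind `mode = "arithmetic"`), with 30 random
draws per size and draw seeds derived from (seed, fold, size, draw).
Accuracies are averaged over draws within fold, then over folds. Group
inference is a one-tailed one-sample t-test against chance (50% for
two-class, 100/3% for three-class — derived from the class count).

### Statistics and gaze screening

`rm_anova()` performs the fully within-subject decomposition (each effect
tested against its subject interaction; two-level factors make sphericity
corrections unnecessary). `holm_bonferroni()` is the step-down
familywise-error rule. `detect_saccades()` classifies maximal stretches
with radius > 1.5° lasting ≥ 150 ms (inclusive at the boundary) as
saccades, after per-run linear detrending and centring on the median
position (the fixation origin is otherwise undefined);
`compare_fixation()` compares per-run mean gaze positions across tasks
with paired t-tests per axis.

### Pipeline

`run_experiment()` composes everything per simulated subject — simulate,
preprocess, map, define patches, estimate single-trial betas, decode every
region × task × classification × test-mode cell, summarize deconvolved
time courses — and aggregates group t-tests and repeated-measures ANOVAs
into a report with the region × classification × task, averaged +
single-trial table layout. Subjects are independent datasets with seeds
derived from the master seed. One structural note: gender is a stimulus
*attribute*, not a condition, so the (condition, task) amplitude map
cannot plant a gender-contingent signal; on default synthetic data the
male/female cells are therefore exact null cells, and planted-signal
demonstrations use the expression classification.

## Numerical and degenerate-input conventions

* Onsets align to volumes by nearest rounding (exact for the default
  integer-TR design).
* Rank-deficient designs: minimum-norm pseudo-inverse plus warning.
* Zero residual variance: contrast t is 0 where the effect is 0, ±Inf
  otherwise; zero-variance group samples at chance give t = 0, p = 0.5.
* Empty feature patches warn rather than error (mirroring threshold
  lowering in practice); decoding cells with empty patches report NA.
* Ties in the phase map argmax resolve to the earliest shift.

## Problem sizes used in the tests

The shipped tests exercise the full pipeline at reduced problem sizes
chosen to keep the suite quick while preserving the structure under test:
null-decoding calibration uses 50 forward-model datasets (six runs, 20
trials per class per run, 40 voxels); phase-recovery sweeps use 8 angles ×
20 noise seeds at CNR 1; the null-cohort calibration runs 50 cohorts of 5
subjects with 24 trials per condition and ~60 V1 voxels. The generator's
*default* configuration remains the full-size protocol (9 subjects, 120
trials per condition, 160-voxel rest region).

## Known limitations

* Voxels have no spatial layout, so nothing spatial (smoothing,
  clustering, surface projection) is modelled or needed.
* No slice-time or motion correction, no anatomical normalization — out
  of scope by design.
* The null calibration of decoding holds for the implemented
  normalization/classification contract; it says nothing about biases of
  other beta-estimation schemes.
* Eccentricity mapping and V1/V2 border finding are not implemented; the
  mouth patch's V1/V2 spanning is flattened into a single region label.
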