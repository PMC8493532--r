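---
title: "Generating labeled synthetic echocardiography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating labeled synthetic echocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echoforge)
```

## The problem

Training a cardiac chamber segmentation network normally requires expert
annotation of thousands of ultrasound frames — slow, costly and
inconsistent across annotators. `echoforge` inverts the process: it starts
from 3D heart geometry whose tissue labels are known by construction,
slices it along anatomically defined echo view planes, and renders
pseudo-ultrasound images whose label masks are pixel-exact by design. An
optional unpaired image-to-image transform (CycleGAN-style) moves the
rendered images toward the appearance of a real scanner, and a U-Net is
trained on the resulting pairs. Every stage is deterministic under a seed
and every emitted sample carries full generation provenance.

## Phantom cohort

Real pipelines of this kind start from a cohort of CT-derived,
tissue-labeled anatomical models (typically around 19). Those models are
not redistributable, so this package ships a parametric phantom generator
that emulates their essential properties: closed, tissue-labeled
compartments (LV blood pool, myocardial shell, LA, RV, RA, aorta, and the
mitral valve as a thin disk) with named anatomical landmarks placed
analytically (apex, mitral valve center, aortic valve center). The
phantoms are assemblies of half-ellipsoids, ellipsoids and tubes — not
biophysical models — which is sufficient because every downstream stage
consumes only labeled geometry plus landmarks.

Two properties are guaranteed by construction rather than estimated:

* **Correspondence.** Every phantom is generated from one template
  topology with per-instance vertex displacement, so a cohort always has
  identical vertex counts and face arrays. Point-distribution modeling
  requires this and real pipelines spend considerable machinery obtaining
  it; here it is free.
* **Watertightness per compartment.** Each labeled compartment is a closed
  surface with positive signed volume, which makes point-in-compartment
  queries on a cut plane exact parity tests.

The default parameters (LV long axis 85 mm, endocardial radius 26 mm, wall
10 mm, etc.) sit in the middle of adult ranges; cohort generation jitters
them uniformly within documented plausible bounds (e.g. LV length 75–95 mm,
wall 7–13 mm). A seed-driven smooth displacement field (default amplitude
0.3 mm) individualises shapes beyond the parametric degrees of freedom.
Neighbouring chambers are kept geometrically disjoint from the epicardial
shell, so thin inter-chamber background gaps can occur where real anatomy
has contiguous tissue; the realism transform stage, not the phantom, is
responsible for appearance.

## Shape model

`align_cohort()` performs rigid generalized Procrustes alignment
(rotation + translation only — scaling is deliberately retained because
overall heart size is a genuine anatomical mode). `fit_pdm()` runs PCA on
the flattened vertex coordinates through the SVD of the centered data
matrix (the dual eigenproblem, since 3V greatly exceeds n). The retained
mode count `k` is the smallest number of leading modes reaching the
variance target, default 0.90 — on a 19-model CT cohort this threshold
yields 9 modes; on phantoms it adapts to however many effective degrees
of freedom the cohort has, which is why the threshold, not the count, is
the configuration parameter.

New shapes are drawn per mode within two standard deviations of the mean.
The bound is hard; the distribution inside it is uniform on `[-2, 2]` SD
by default. A uniform is the least-assuming distribution that guarantees
the bound; a truncated Gaussian is available
(`sample_shape(distribution = "truncnorm")`) for users who prefer mass
concentrated near the mean. All mode coefficients are sampled jointly per
shape; `mode_sweep()` provides the classical one-mode-at-a-time
visualisation series separately.

## View planes and slicing

The apical four-chamber plane is defined exactly: the plane through the
apex, the mitral valve center and the aortic valve center. The in-plane
"down" axis points from apex to mitral valve so the apex renders at the
top of the raster. The two-chamber plane rotates this frame 70° about the
LV long axis (counter-clockwise seen from the apex); 70° rather than the
textbook 60° probe rotation gives a cleaner cut on these models, and the
angle is a parameter. Acquisition variability is emulated by random plane
rotations about the LV long axis (±10°) and an in-plane short axis (±5°),
both through the LV centroid — producing foreshortened and off-plane
slices. The ranges are package defaults chosen to give visible but not
pathological foreshortening, and are fully configurable.

Rasterization labels each pixel center by the compartment containing it.
For a point in the cut plane this is a 2D parity test against the
compartment's plane-intersection segments, evaluated as a vectorized
scanline — mathematically identical to a 3D point-in-closed-surface test
for watertight compartments, and far cheaper. Precedence resolves nesting:
blood pools over myocardium over the valve disk, so no pixel inside the LV
pool is ever labeled myocardium. The default raster is 256×256 at
0.6 mm/pixel; label areas converge quadratically with resolution (the test
suite checks the factor-of-four area scaling when the spacing is halved,
on structures more than a few pixels thick — a 1.5 mm valve disk at
2.5 px is excluded from such checks by nature).

## Pseudo-ultrasound rendering

A rendered pair is produced by: mapping tissue codes to gray levels
(pools ≈ 0.10–0.15, myocardium 0.70, background 0 — configurable; chosen
to mimic the structural appearance of B-mode images, which no published
values pin down), masking with a sector ("cone") whose apex sits at the
top of the image, choosing a crop (whole-heart or LV-focused with equal
probability), and applying one affine chain — random rotation ±8°,
anisotropic squeeze 0.85–1.15, and a fitted scale/translation — to both
rasters: bilinear for intensity, nearest-neighbor for labels, because
label codes are categorical. The scale is found by shrinking until the
crop's region of interest fits inside the sector for some vertical
placement (an LV-focused crop places the LV apex near the sector apex and
spans ~70% of the depth). The region-of-interest labels are verified to
lie inside the cone, with up to 20 transform re-draws; structures outside
the ROI (the LA in an LV-focused crop, exactly as in clinical LV-focused
views) are clipped at the sector boundary. Every emitted pair therefore
satisfies `image = label = 0` outside the cone, exactly.

Uniform noise on `[-a, a]` (default a = 0.08) is added inside the cone,
1–3 angular shadow sectors (width 5–20°, attenuation 0.3–0.7) emanate
from the cone apex, and the image is blurred with a Gaussian kernel
(default σ = 2 px — about the minimum that removes staircase edges at
256²). These parameter ranges are package defaults standing in for
unpublished acquisition-augmentation details; they are all exposed in
`render_config()`, which also carries named profiles (`cloudy`,
`high_gain`) emulating dataset-to-dataset appearance differences. Labels
are never touched by noise, shadows or blur.

Dataset arithmetic is exact: `render_dataset()` emits
`models × slices_per_model × pseudo_per_slice` pairs (99 × 3 × 3 = 891
for the shape-expanded configuration; 19 × 5 × 9 = 855 for the
no-expansion variant), re-drawing failed placements under fresh sub-seeds
so the count never drifts.

## Realism transform and segmentation

No deep-learning framework is assumed: the package carries a compact CNN
engine (im2col convolutions in C++, explicit backprop, Adam) whose
gradients are verified against finite differences in the test suite. The
transform is a CycleGAN in its canonical configuration — least-squares
adversarial loss, cycle weight λ = 10, identity weight 0.5λ, patch
discriminators, Adam at 2e-4 with linear decay over the second half of
training, 200 epochs with checkpoints every 5 — except that the generators
are U-Nets (8 down-sampling levels at 256²; the level count must divide
the image size and is reduced for smaller test images). Checkpoint choice
defaults to the final checkpoint; a per-checkpoint sample can be exported
for manual review, since human selection around epoch 180 is reported not
to matter much in practice. Applying the transform replaces images and
copies label rasters bit-identically.

The segmenter is the same U-Net family trained 30 epochs with
cross-entropy. Checkpoint selection uses **simplicity**,
`S_p = sqrt(4π·Area)/Perimeter` — 1 for a disk, lower for ragged masks —
computed on predictions over an *unlabeled* selection set: the checkpoint
with the highest median simplicity is chosen (ties to the later epoch;
an empty predicted mask scores 0 to penalise degenerate checkpoints).
Selection deliberately receives images only, so it can run on real,
unannotated data; synthetic-validation Dice is not used because every
checkpoint scores highly there.

## Evaluation metrics

* **Dice** `D = 200·|A∩B| / (|A|+|B|)` on pixel counts (0–100). Two empty
  masks return 0 with a warning — the conservative reading.
* **Bias** `B = 200·(Area_pred − Area_ref)/(Area_pred + Area_ref)`:
  antisymmetric, bounded by ±200; a systematically nonzero dataset bias
  flags annotation-style differences rather than shape errors.
* **Simplicity** uses the sub-pixel iso-contour perimeter: contours are
  marching-squares level-0.5 lines of the mask after convolution with a
  small Gaussian (σ = 0.7 px). Contouring the raw binary field instead
  would overestimate a disk's perimeter by ~5% (and pixel-edge counting
  by ~11%); with the smoothed field a radius-50 disk scores within 2% of
  the analytic 1.0. For masks only a few pixels across, where smoothing
  would erase the iso-level, the raw field is contoured instead — such
  tiny masks can score slightly above 1.
* **Mean contour distance** `d_m` averages point-to-segment distances
  between the two contours, symmetrized (each direction averaged); a
  one-directional variant is a flag. Values are in pixels.
* **Aggregation** reports medians with the *unscaled* median absolute
  deviation `MAD = median(|X_i − median(X)|)` (no 1.4826 consistency
  factor), because segmentation score distributions are rarely normal.
* **Method comparison** is the two-sided paired Wilcoxon signed-rank
  test; zero differences are dropped (classic treatment; a Pratt variant
  keeps them in the ranking), the exact distribution is used up to
  n = 25 without ties, and a tie-corrected normal approximation beyond.

## Problem sizes, determinism and limitations

The test-suite and acceptance runs use reduced problem sizes chosen as
the package's own working points: 128² rasters for the dataset-arithmetic
and overfit checks, 64² with two-level U-Net generators, a three-level
patch discriminator and 40 epochs for the toy transform check,
10-pair/30-epoch overfit training. Adversarial training at this miniature
scale is init-sensitive: most seeds converge decisively, a minority move
the domain gap only partway within 40 epochs (longer training continues
to close it). All randomness flows from
explicit integer seeds through deterministic sub-seed streams, so every
dataset, training run and metric value is bit-reproducible.

What passing tests do *not* show: phantom anatomy is idealized (no
trabeculation, no pericardium, disjoint chamber walls, no pathology), the
pseudo-texture model has no speckle physics, and the desk-scale CycleGAN
demonstrates the mechanism (an intensity-domain shift) rather than
scanner-grade realism. Results on real clinical images depend on training
the transform against a real image set at full scale, which is out of
scope for the automated checks.
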