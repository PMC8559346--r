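---
title: "Classifying sclerotic glomeruli in PAS-stained kidney biopsies"
author: "glomclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying sclerotic glomeruli in PAS-stained kidney biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Assessing a donor kidney before transplantation includes estimating the
fraction of scarred (sclerotic) glomeruli on a PAS-stained biopsy slide.
Pathologists outline each glomerulus and label it sclerotic or
non-sclerotic; doing this over a whole slide is slow and subjective.
`glomclass` implements a computer-aided classification workflow that takes
pre-cropped glomerulus images and predicts the label from hand-crafted
morphological and texture features with a cross-validated shallow
neural-network ensemble.

The two classes differ visibly. A healthy (non-sclerotic) glomerulus is an
elliptic structure in which the capillary tuft is separated from Bowman's
capsule by the white Bowman's space; capillary lumens appear as white blobs
and cell nuclei as small dark-blue dots over a pink-magenta mesangial
matrix — the so-called pomegranate texture. In glomerulosclerosis the
extracellular matrix obliterates the capillary lumens and the Bowman's
space shrinks or disappears, leaving a comparatively homogeneous
pink-magenta disk.

## Workflow

For every crop the package computes a 150-value descriptor:

1. **Morphology (2 features).** Three parallel segmentations of the white
   regions — the RGB green channel and the complement of the CMYK magenta
   channel thresholded at 190, and a CIELAB k-means clustering (k = 5, 3
   restarts, keeping the cluster with the brightest mean luminance) — each
   cleaned by binary median filtering, erosion and dilation (disk of radius
   2, configurable 1-3) and refined by a region-based active contour run
   for 200 iterations. The masks are fused by majority vote (a pixel
   survives if at least two masks contain it), components smaller than
   1000 px are removed, and the result is intersected with a centered disk
   of diameter 7/8 of the smaller image side. The features are the white
   area fraction (mask area / image area) and the equivalent radius
   `sqrt(hull_area / pi)` of the convex hull of the mask.
2. **Multi-radial colour LBP (120 features).** Rotation-invariant uniform
   (riu2) local binary patterns with 8 bilinear-interpolated circular
   neighbors at radii 1, 3, 9 and 27, on each RGB channel; each radius
   contributes a normalized 10-bin histogram (9 uniform labels plus the
   non-uniform catch-all).
3. **Haralick block (28 features).** Grey-level co-occurrence matrices at
   distance 1 in the four directions (0, 45, 90, 135 degrees) on the
   luminance image quantized to 64 levels; the 14 classic Haralick indices
   per direction (56 values) are reduced to their per-index mean and range.

Features are z-score standardized and reduced by PCA, keeping the smallest
leading basis that explains 99.9% of the variance. A 10-fold ensemble of
one-hidden-layer networks (tanh hidden units, softmax output,
cross-entropy loss, scaled conjugate gradient) is trained on the reduced
features; each fold keeps the best of 5 random initializations by
validation MCC, selects a decision threshold on its validation ROC curve,
and the ensemble predicts by hard majority voting.

## Class imbalance

Sclerotic glomeruli are rare (about 1 : 5.5 in the data regime this
workflow targets), so accuracy alone is uninformative and the softmax
output cannot be cut at 0.5. Two measures address this:

* the Matthews correlation coefficient — the correlation between predicted
  and true labels, 1 for perfect prediction, 0 for a random predictor,
  -1 for complete disagreement — drives both initialization selection and
  the hidden-size sweep;
* the per-fold decision threshold is chosen on the validation ROC curve,
  either as the point touched first by a line of slope
  `n_negative / n_positive` sliding down from the perfect corner
  (Approach A, `threshold_approach_a()`) or as the point minimizing the
  Euclidean distance `sqrt((1 - sens)^2 + (1 - spec)^2)` to the perfect
  corner (Approach B, `threshold_approach_b()`). Approach B is the
  default: it trades a little precision for higher recall, which is the
  right trade when missing a diseased glomerulus is the costlier error.
  Voting ties (5 votes against 5 with k = 10) resolve toward sclerotic
  for the same reason.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 190 | whiteness cut on the 0-255 channel value |
| `clean_radius` | 2 px | disk radius of median/erode/dilate cleaning |
| `ac_iterations` | 200 | active-contour iterations |
| `kmeans_k`, `kmeans_replicates` | 5, 3 | CIELAB clustering |
| `min_region_px` | 1000 px | smallest surviving mask component |
| LBP radii | 1, 3, 9, 27 px | multi-radial texture scales |
| `glcm_levels`, `glcm_distance` | 64, 1 | co-occurrence quantization/offset |
| `variance_threshold` | 0.999 | PCA retained cumulative variance |
| `hidden_size` | 27 | hidden units per fold network |
| `k_folds` | 10 | cross-validation folds |
| `inits_per_fold` | 5 | random restarts per fold |
| `early_stop_window` | 6 epochs | validation-fail patience |
| `val_fraction` | 0.15 | stratified inner validation share |
| `test_fraction` | 0.2 | biopsy-level test share |

All of them live in one `pipeline_config()` object; every run writes a
resolved copy of the configuration next to its artifacts.

## Design choices where the procedure was genuinely open

* **Bounding boxes.** The 1.1 overestimation factor is applied per side
  about the center of the tight box (symmetric context capture), rounded
  outward to whole pixels and clamped — not padded — at image borders, so
  no tissue is fabricated. Rectangles are 0-based and half-open, which
  keeps area arithmetic exact.
* **Biopsy-level split.** Whole biopsies are assigned to the test set so
  that no biopsy straddles the split; among all feasible assignments the
  one whose test fraction is closest to the target is chosen (exhaustive
  enumeration up to 15 biopsies, seeded greedy search beyond), ties broken
  at random under the seed.
* **CMYK conversion.** No colour profile accompanies the naive device
  conversion `K = 1 - max(R,G,B)/255`,
  `M = (1 - G/255 - K)/(1 - K)` (with `M = 0` at pure black); the
  "complement of magenta" plane is `255 * (1 - M)`. One consequence worth
  knowing: neutral grays have `M = 0`, so their complement is 255 and the
  magenta mask alone cannot reject a gray background — the majority fusion
  with the green-channel and CIELAB masks is what makes the segmentation
  robust.
* **CIELAB.** sRGB primaries with the D65 white point, the standard
  assumption for stain photographs.
* **Cleaning order.** Median (binary majority over the disk), then
  erosion, then dilation: an opening-style sequence that removes speckle
  without growing blobs. The operators and the disk are fixed; the order
  is our choice.
* **Active contour.** The region-based (Chan-Vese) energy in its
  morphological formulation: boundary pixels are reassigned to the region
  with the closer mean and one binary median pass per iteration acts as
  the curvature term. It is unconditionally stable, needs no step-size or
  gradient tuning, and runs on the same channel image that was
  thresholded (luminance for the k-means mask). The update is a
  deterministic map of the mask, so when an iteration reproduces a
  previous state the remaining iterations are resolved analytically
  (fixed point or period-2 cycle parity) — the result is exactly the
  200-iteration state.
* **Circular AND.** The final filter is a centered disk of *diameter*
  `(7/8) min(H, W)`: a radius of that magnitude would circumscribe the
  whole image and filter nothing, so the diameter reading is the only one
  with any effect.
* **Connectivity.** 8-connectivity for small-region removal, the common
  default in blob analysis.
* **k-means.** Squared Euclidean distance on raw (a, b); each of the 3
  replicates starts from distinct pixel values sampled under the seed and
  the restart with the lowest total within-cluster sum of squares wins,
  making the mask reproducible.
* **LBP.** 8 neighbors at every radius — the 10-bin histogram width forces
  P + 2 = 10 — with bilinear interpolation for off-grid samples; offsets
  within 1e-9 of a grid point are snapped to it so that exact-neighbor
  comparisons are not perturbed by trigonometric rounding.
* **Haralick.** Luminance (Rec. 601) input, 64 levels, distance 1 —
  configurable, since the choice is conventional. Sum variance is taken
  about the sum average (the common modern convention). All logarithms
  guard `0 log 0 = 0`; on a single-level matrix the correlation-type
  indices are defined as 0; the maximal correlation coefficient maps
  non-finite eigenvalue results to 0 so feature vectors stay finite.
* **PCA scope.** The preprocessing can be fit on the training portion only
  (default — no information leakage) or on the whole dataset, which is
  label-free and therefore defensible; both scopes are exposed because the
  component counts they retain are very close in practice.
* **Variance convention.** Population (1/N) denominators for the z-score;
  any fixed convention works as long as it is declared, and the PCA is
  scale-consistent either way.
* **Metrics at zero denominators.** A metric whose denominator vanishes is
  reported as 0 and flagged, matching the "random predictor = 0" reading
  of the MCC.
* **Per-fold thresholds.** Each fold network carries its own validation
  threshold rather than sharing a pooled one; fold-wise validation
  summaries then mean over folds cleanly.

## The synthetic generator

Clinical slides cannot ship with a package, so `generate_dataset()` draws
PAS-like crops that exercise exactly the cues the features measure:
elliptic capsule, near-white annular Bowman's space, white lumens and blue
nuclei over a mottled matrix for the non-sclerotic class; a homogeneous
filled ellipse with at most one residual lumen for the sclerotic class.
Colours were fixed once so that stained tissue and white structures
straddle the 190 threshold realistically: matrix around RGB (200, 120,
160), background (210, 140, 180), nuclei (60, 60, 140), whites at 230 or
above, Gaussian pixel noise of sd 8 (4 for the homogeneous sclerotic
matrix). Each simulated biopsy carries one additive colour offset
(strength set by `saturation_jitter`, default 0.15) emulating
slide-to-slide staining variability, and `artifact_rate` injects
edge-truncated glomeruli or dark stain blobs, flagged in provenance, to
reproduce the known failure modes of the approach. Defaults are 10
biopsies of 30 crops at a 5.5 : 1 class imbalance, 128 px crops with
capsule semi-axes of 38-50 px.

What the generator does **not** emulate: real capillary networks and
mesangial architecture, stain diffusion, out-of-focus regions, compression
artifacts, or the long tail of borderline partial-sclerosis morphologies.
Passing the end-to-end tests therefore shows that the implementation is
faithful and that the features separate the designed cues; it does not
certify clinical performance on real slides.

## Problem sizes in the test suite

The suite validates the descriptors against independent naive-loop oracles
on 64 x 64 random images, the ROC thresholds against brute-force
minimization, and the MCC against the Pearson correlation of reconstructed
label vectors. End-to-end checks run the default 10 x 30 synthetic dataset
with a biopsy-level 80/20 split across 3 master seeds and require a mean
test MCC of at least 0.9; structural pipeline tests use reduced sizes
(2-5 biopsies, 3-12 crops each) chosen to exercise every artifact without
inflating runtimes.

## Known limitations

* The workflow classifies given crops; it does not detect glomeruli in
  whole-slide images, parse SVS pyramids, or normalize stains.
* The 190 threshold and the colour conversions assume 8-bit sRGB-like
  input; heavily over- or under-stained slides will shift the white masks.
* Crops smaller than 55 px per side cannot support the radius-27 LBP and
  are rejected.
* The maximal correlation coefficient is numerically fragile on
  near-degenerate co-occurrence matrices; its guarded fallback (0) keeps
  vectors finite but discards information in those rare cases.
* Partial (segmental) sclerosis is not modelled: the labels are binary.

## A minimal run

```{r example}
library(glomclass)

cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "glom_run")
res$metrics$metrics

# stability over repeated runs
stab <- run_stability(cfg, n_runs = 3)
stab$summary
```
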