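---
title: "Quantifying cerebral collateral circulation from CTA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral collateral circulation from CTA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In acute ischemic stroke, the quality of leptomeningeal collateral
circulation — secondary vascular routes that keep tissue alive distal to an
occlusion — is a key determinant of treatment eligibility and outcome.
Radiologists grade collaterals visually on CT angiography (CTA) with
ordinal scales (Tan 0–3, Menon 0–5, rLMC 0–20), a process that is slow and
shows substantial inter-observer variability. `collateralq` implements an
automated alternative: segment the vessels in both middle-cerebral-artery
(MCA) territories, then express collateral quality as a continuous volume
ratio,

\[
\mathrm{qCS}(\%) \;=\; 100 \times \frac{V_\text{affected}}{V_\text{healthy}},
\qquad \mathrm{qCS} \ge 0 ,
\]

where \(V_\text{affected}\) and \(V_\text{healthy}\) are the segmented
vessel volumes (mm³) in the affected- and healthy-hemisphere territories.
The affected side is a clinical input, never inferred from the image. The
score may exceed 100 when the affected side carries more vessel volume
than the healthy side. A healthy-side volume of zero leaves the score
undefined; the package raises an explicit degenerate-case error rather
than returning infinity or a silent zero.

The continuous score is discretized three ways, with all interval upper
ends closed:

* binary: poor if qCS ≤ 49, good if qCS > 49;
* quaternary (0–3): cuts at 5, 49, 95;
* six-class (0–5): cuts at 5, 25, 49, 75, 95.

The 5/49/95 cutoffs are a refinement of the nominal 0/50/100 grade
boundaries of the four-level visual scale: `sweep_thresholds()` reproduces
the refinement procedure, scanning 1-percentage-point candidates across a
10-point window around each nominal boundary and scoring each candidate's
dichotomization against reference labels by accuracy, with ties broken by
sensitivity + specificity and then by proximity to the nominal value. The
full candidate tables are always returned, because the combination rule
for the three criteria is a design choice: accuracy is primary here, a
Youden-style tie-break second, proximity last. Candidates dichotomize with
the same strict rule as the grading itself (positive iff qCS > candidate);
a consequence worth knowing is that a candidate exactly equal to a
positive case's score classifies that case negative.

## Synthetic cerebrovascular phantoms

No public cohort accompanies the quantification protocol this package
implements, so all testing runs on seeded synthetic phantoms
(`generate_phantom()`, `generate_cohort()`). A phantom is built from:

* **Territories.** Fixed half-ellipsoid MCA-territory masks, one per
  hemisphere, exact mirror images of each other about the midsagittal
  plane. Deterministic and trivially mirror-consistent; no anatomical
  atlas is attempted.
* **A healthy-hemisphere tree.** A random branching tube: a trunk random
  walk with angular perturbation bounded by the `tortuosity` parameter,
  plus `n_branches` side branches attached at random points with tapering
  radii (`radius_range_mm`, default 0.8–2.0 mm). Centerlines are
  rasterized as metric balls in millimetre space, so anisotropic voxels
  (default 0.5 × 0.5 × 0.625 mm, the axial spacing matching thin-slice
  CTA acquisition) are handled exactly.
* **An affected-hemisphere tree with controlled volume.** The healthy
  centerlines are mirrored across the midsagittal plane and their radii
  scaled by a single factor \(s\). Because metric balls nest, the affected
  voxel set grows monotonically with \(s\); the package computes, once per
  phantom, the field \(D(v) = \min_k \|v - p_k\|/r_k\) over mirrored
  centerline points and picks \(s\) as the \(m\)-th order statistic of
  \(D\) inside the affected territory, \(m = \text{round}(r \cdot
  |H|)\) for target ratio \(r\) and healthy voxel count \(|H|\). This is
  the closed-form solution of the bisection-on-a-scale-factor idea: it
  hits the target ratio to within half a voxel (tolerance ±2 percentage
  points is enforced, and generation errors out if the grid cannot support
  the requested ratio), is exactly monotone in the target, and at \(r = 1\)
  the affected mask is the bit-exact mirror of the healthy one, so the
  realized ratio is exactly 1.
* **Intensities.** Vessel voxels draw uniformly from 150–450 HU and the
  background from N(35, 10²) HU. These defaults straddle the annotation
  display window (level 100, width 600 HU) and keep mean vessel intensity
  at least three noise standard deviations above background; they are
  fixture choices for a contrast-filled artery against parenchyma, not
  measurements of any scanner.

What the phantoms deliberately do **not** emulate: skull and bone, veins,
contrast-bolus timing, Circle-of-Willis topology, pathology other than a
volume deficit, and partial-volume blur. Passing tests therefore
demonstrate that the pipeline's *computational* contracts hold — exact
volume accounting, ratio control, reproducibility, learnability of bright
tubular structure — not that the trained network generalizes to clinical
CTA.

All randomness flows from explicit integer seeds; per-case seeds derive
reproducibly from a master seed, and regenerating a cohort with the same
seed is bit-identical.

## Preprocessing

`normalize_window()` maps the annotation display window
\([-200, 400]\) HU (level 100, width 600) linearly onto \([0, 1]\) with
clipping — the same window under which the vessels would be traced.

`align_midline()` implements rigid self-alignment: since hemisphere
comparison needs only a consistent midsagittal plane, the registration
target is the volume's own sagittal mirror image, and the objective is the
Pearson correlation between the transformed volume and its mirror. Two
numerical points matter. First, three of the six rigid parameters
(translations along the coronal/axial axes and rotation about the sagittal
axis) commute with the mirror and are unidentifiable from this objective;
they are pinned at zero, making the returned transform the minimum-norm
maximizer and the identity for an already-symmetric volume. Second,
trilinear resampling at fractional offsets smooths noise and would
spuriously raise the correlation of any noisy volume; the objective is
therefore evaluated on a 3³ box-smoothed copy, and the identity is kept
unless the optimum improves the mirror correlation by more than `min_gain`
(default 0.005, roughly ten times the residual noise-smoothing artifact
observed on phantoms).

`split_hemispheres()` partitions the grid at a sagittal midline index
(radiological convention, low sagittal index = patient right). For an even
sagittal extent the split is exact; for an odd extent the single midplane
sheet belongs to neither hemisphere, so the partition never lets one
voxel count twice.

## The segmentation network

Vessel segmentation uses a two-level nested U-shaped network: an outer
encoder–decoder whose every stage is itself a residual U-block (RSU) that
pools, convolves and upsamples internally before adding a residual
connection. Each decoder stage and the deepest encoder stage emit a side
probability map; a 1×1 convolution over the side logits produces the fused
map (deep supervision). Every convolution is 3×3 with batch normalization
and ReLU; the deepest stages use dilated RSUs without internal pooling.

Because no deep-learning framework is available to R here, the network is
implemented in the package's own C++ (Rcpp/RcppArmadillo): convolutions as
im2col + BLAS GEMM, explicit reverse-mode gradients for every operator
(verified against finite differences in the test suite), and Adam in R on
a flat parameter vector. All state — weights, Adam moments, batch-norm
running statistics — lives in plain R numeric vectors, which makes
checkpointing, seeding and bit-reproducibility straightforward.

Sizes are configuration, not constants. The `"full"` preset mirrors the
reference architecture (6 stages, 64 base channels, RSU depths
7-6-5-4-4-4, two dilated bottom stages, ≈57 M parameters). The `"scaled"`
preset used throughout testing has 4 stages, 8 base channels, depths
5-4-3-2 with one dilated bottom stage (≈103 k parameters) and trains on
one CPU in minutes. Decoder stage channel plans are derived from the
encoder plan; the only intentional departure from the reference channel
table is the first decoder stage's internal width (derived as half the
stage width rather than a special-cased 16), which keeps the plan a pure
function of the configuration.

Decisions the underlying protocol leaves open, and what this package
does about them:

* **Loss.** Binary cross-entropy per map (per-pixel mean), summed with
  equal weights over the fused and all side maps; evaluated in logit space
  for stability. Exposed as `deep_supervision_loss()`.
* **Operating point.** Fused probability strictly greater than 0.5 (a
  probability exactly at the threshold is background); configurable in
  `predict_mask()` and the CLI.
* **2D vs 3D.** Inference is axial slice-wise (the annotation unit is the
  axial slice), restacked to a 3D mask carrying the input spacing. Slices
  not divisible by \(2^{\text{stages}-1}\) are reflect-padded and cropped
  back.
* **Validation DSC granularity.** Volume-wise: the per-case Dice of the
  restacked predicted mask, averaged over validation cases.

## Training protocol

`train_config()` defaults encode the development protocol: Adam, learning
rate 1e-4 with batch size 8 (the winning cell of the 3 × 3 grid
{1e-3, 1e-4, 1e-5} × {8, 16, 32}), up to 500 epochs, early stopping after
20 epochs without improvement, 5-fold case-level cross-validation.
"Plateauing" is read as no *strict* improvement of the best validation DSC
for `patience_epochs` consecutive epochs — the simplest faithful reading,
with no minimum delta; `early_stop_trace()` exposes the rule on arbitrary
histories, and the returned model always carries the best epoch's weights,
never the last.

`make_folds()` partitions cases (never slices — slice leakage between
train and validation is checked and refused) with round-robin dealing
within strata, the dealing position carried across strata so fold sizes
differ by at most one.

Augmentation (`augment_spec()`): horizontal/vertical flips at p = 0.5
each, multiplicative brightness ±20 %, contrast scaling 0.8–1.2 about the
slice mean, rotation ±10°, zoom 0.9–1.1. Brightness is multiplicative and
contrast re-scales about the mean because the protocol names the ranges
but not the operators; both are documented here as package choices and
configurable. Geometric transforms apply jointly to image (bilinear) and
mask (nearest-neighbour); photometric transforms touch the image only,
re-clipped to [0, 1]. Every range contains the identity, and a collapsed
spec reproduces its input bit-exactly.

`grid_search_cv()` scores each (learning-rate, batch-size) cell by the
mean best-validation-DSC over folds and returns the winning cell's best
fold as the final model — one fold's weights, the literal reading of the
protocol's selection rule, rather than a retrain on all data. Ties go to the
smaller learning rate, then the smaller batch size (`select_winner()` is
pure and unit-tested). Failed cells are excluded and logged.

## Problem sizes and numerical choices

The shipped study conditions are sized for a single CPU:

* default phantom grid 48 × 48 × 24 voxels (tests use 32 × 32 × 16),
  spacing 0.5 × 0.5 × 0.625 mm, 6 branches per tree;
* the overfitting check trains the scaled preset on the 5 most
  vessel-rich slices of one phantom for up to 200 epochs (training DSC
  ≥ 0.90 is reached in roughly 75 epochs, about half a minute);
* the end-to-end run generates 12 phantoms stratified over the four
  quaternary grade intervals, trains on 6 + 2 validation cases using every
  second axial slice (learning rate 1e-3, batch 8, ≤ 20 epochs, patience
  8, no augmentation), segments the 4 held-out cases and evaluates —
  about half a minute, with held-out per-case Dice roughly 0.65–0.9 and
  predicted-mask qCS within ±10 percentage points of the ground-truth
  qCS in the runs the test suite executes.

The slice subsampling, epoch cap and augmentation-off defaults of
`pipeline_config()` are the scaled run's own design; the package-level
`train_config()` defaults remain the full protocol values.

Batch normalization uses biased batch variance during training and
running averages (momentum 0.1) at evaluation, so inference is independent
of batch composition. Weight initialization is He-normal, a pure function
of (configuration, seed). Degenerate statistics (zero denominators,
single-class references, zero rank variance, constant rating matrices)
are reported as `NA` flagged with a reason, never silently coerced.

## Agreement statistics

`dice()`, `confusion()`, `binary_metrics()`, `multiclass_accuracy()`,
`per_class_recall()`, `roc_auc()`, `spearman_cor()` and `icc21()` cover
the evaluation suite. Conventions worth noting:

* empty-vs-empty Dice is defined as 1 (perfect agreement on absence) and
  flagged, since conventions differ;
* the positive class for binary metrics is *good* collateral status
  (qCS > 49);
* AUC is the rank-based (Mann–Whitney) form with ties counting ½,
  identical to trapezoidal ROC integration, with the Hanley–McNeil
  normal-approximation CI; the continuous qCS is the score that feeds it,
  the reference label the dichotomized grade;
* Spearman's ρ is Pearson on mid-ranks with the t approximation;
* ICC(2,1) is the two-way random-effects, absolute-agreement, single-
  measure form, \((\mathrm{MSR} - \mathrm{MSE}) / (\mathrm{MSR} + (k-1)
  \mathrm{MSE} + k(\mathrm{MSC} - \mathrm{MSE})/n)\), with the F-based
  confidence interval. Absolute agreement penalizes systematic offsets
  between raters, which the consistency form would forgive.

Every statistic is checked in the test suite against an independent
brute-force oracle (pair enumeration for AUC, explicit ANOVA sums for ICC,
definitional formulas for MCC/F1, the classical \(6\sum d^2\) formula for
Spearman) on hundreds of random instances, plus hand-computed fixtures.

## Known limitations

* Phantom realism is intentionally minimal (see above); DSC values
  obtained on phantoms say nothing quantitative about clinical CTA.
* The mirror-symmetry alignment assumes the head is already roughly
  centred; it has no skull landmarks and searches a ±5 voxel window.
* MCA-territory delineation is taken from supplied masks (or the
  whole-hemisphere fallback, which is recorded in the output); no atlas
  registration is attempted.
* The full-size network preset is provided for completeness and trains
  only at realistic cost on hardware with far more compute than the test
  environment assumes; no pretrained weights ship with the package.
* `roc_auc()`'s CI is a large-sample approximation; at the n = 4 scale of
  the end-to-end demonstration it is indicative only.
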