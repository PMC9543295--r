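---
title: "Comparing ground-truth labeling strategies for prostate MRI lesion detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ground-truth labeling strategies for prostate MRI lesion detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostlab)
```

## The problem

Machine-learning models that detect and grade prostate cancer on MRI are
only as good as the labels they are trained on, and those labels can come
from very different places: radiologists outlining suspicious lesions during
clinical reads, pathologists outlining cancer on post-operative whole-mount
histopathology, or an automated Gleason-grading model (a "digital
pathologist") whose per-pixel histologic grade predictions are mapped onto
MRI through registration. Radiologist outlines systematically miss
MRI-invisible tumors (roughly a fifth of lesions), under-estimate cancer
extent, and skip slices; pathologist outlines capture full extent on the
slices they annotate but carry no grade information; digital-pathologist
grade maps are dense and graded but inherit registration and resolution
artifacts.

`prostlab` implements the full comparison methodology for these labeling
strategies: derivation of four label types from a per-voxel grade map and
human outlines, 3D morphological lesion formation with clinical volume
filtering, small trainable multi-class segmentation models ("digital
radiologists"), sextant-based lesion-level evaluation, and a seeded
synthetic phantom generator so the entire pipeline runs end-to-end on
reproducible data with known ground truth.

## Label model

All labels live on a common integer-coded grid: 0 outside the prostate,
1 normal tissue, 2 indolent cancer (Gleason pattern 3), 3 aggressive cancer
(Gleason pattern 4 and above; regions where patterns 3 and 4 overlap are
collapsed to aggressive upstream of this package's codes).

**Lesion formation.** Pixel-level annotations become 3D lesions by
morphological closing with a structuring element of three stacked in-plane
disks of radii 0.5, 1.5 and 0.5 mm (converted to pixels by round-half-up
with a minimum radius of 1 pixel; the element spans three adjacent slices
regardless of slice spacing, because it is defined slice-wise), followed by
3D connected-component labeling. Lesion volume is the exact product
`LV = PSx * PSy * Dz * NL`, with `NL` counted on the closed mask; lesions
below 250 mm^3 are discarded (half the 500 mm^3 clinical-significance
volume of PI-RADS v2), with exactly 250 mm^3 kept.

**Classification (the 1% rule).** A lesion with at least 1% aggressive
voxels is aggressive; otherwise at least 1% indolent voxels makes it
indolent; otherwise it is benign. Lesions confirmed by targeted biopsy
instead map grade groups: group >= 2 is aggressive, group 1 indolent, a
benign biopsy means normal tissue.

**The four strategies.**

* `LRad` — radiologist outlines, each annotated component closed
  separately (outlines from different lesions are never merged across the
  midline), volume-filtered, then classified by the grade-map voxels inside
  the outline; benign-classed outlines remain normal tissue.
* `LPath` — pathologist cancer outlines, processed identically.
* `LLesionDPath` — lesions formed directly on the grade map's cancer
  voxels, each kept lesion painted uniformly with its class.
* `LPixelDPath` — the same lesion footprints, but per-voxel grade codes are
  copied inside each kept lesion, so mixed lesions retain distinct
  aggressive and indolent components — the one thing no human-annotated
  label type can represent.

Voxels added by closing carry no grade code; lesion-level labels give them
the lesion's class, and `LPixelDPath` gives them the majority cancer code
within the structuring-element neighbourhood (ties resolved aggressive, for
consistency with the overlap rule). The alternative — leaving them
unlabeled — would make the pixel-level and lesion-level footprints differ,
which would confound the footprint-controlled comparison.

## Sextant-based lesion-level evaluation

Detection performance is scored per patient on lesion-level units. True
positives and false negatives come from ground-truth lesions (one positive
unit per lesion of the task class, scored by the maximum predicted task
probability over its voxels); true negatives and false positives come from
sextants: the prostate is split into left/right halves at the mask's
x-centroid and each half into three contiguous slice groups (base, mid,
apex) of sizes differing by at most one, remainder assigned base-first.
Sextants containing no task-positive ground-truth voxel contribute negative
units; sextants overlapping a positive lesion are removed from the negative
pool so the same territory is never counted both ways.

Metrics: rank-based (Mann-Whitney) ROC-AUC with ties counting 1/2,
undefined when a patient has no positive or no negative units; Dice overlap
of the hard argmax task masks; sensitivity and specificity at the operating
point induced by the argmax segmentation (a positive lesion counts as
detected when the predicted task mask touches it; a sextant is clean when it
contains no predicted task voxel). Cohort summaries are means with
population standard deviations (ddof = 0); undefined patient values are
excluded and the contributing `n` reported — they are never silently zero.
Tasks: cancer (codes 2 or 3), aggressive (3), indolent (2). For
pixel-level labels the positive units of a task are the connected
components of that task's mask, so a mixed lesion contributes its
aggressive component to the aggressive task.

Three unit-scoring conventions (`max`, 95th percentile, `mean`) are
available; `max` is the default. These conventions, the 26-connectivity
default, and the argmax operating point are declared package conventions:
they are the common choices in lesion-level detection work, and each is
isolated behind a single argument so sensitivity to them can be probed.

## Digital radiologists

The trainable models are compact 2.5D encoder–decoder convolutional
networks mapping T2w and ADC slices to per-pixel class probabilities
(softmax over normal/indolent/aggressive). Three consecutive slices of both
modalities form 6 input channels; the `deeplab_like_2d` variant takes a
single slice (2 channels) and uses a dilated bottleneck; `unet_like` adds
skip connections; `branched_unet_like` has two decoder heads (cancer
vs. normal, aggressive vs. indolent) merged into the 3-class output.
Training minimizes class-balanced cross-entropy over prostate voxels only —
voxels outside the prostate contribute neither loss nor gradient (verified
by a numerical gradient check in the test suite) — with the Adam optimizer
and per-slice mini-batches under case-level fold assignment, so no patient
leaks between folds. Class weights are inverse class frequencies over
prostate voxels of the training set, normalized to mean 1 and capped
(default 10); per-dataset balancing is the default, matching the usual
practice when batches are small. Intensities are z-score normalized within
the prostate before stacking.

The `"full"` preset keeps the full-scale conventions (batch 22, 30
epochs, five folds, learning rates 1e-4 / 1e-5 / 1e-4 / 1e-3 for the
spcnet/unet/branched/deeplab variants); the `"desk"` preset (width 8,
batch 8, 3 epochs, learning rate 1e-3) is sized for single-CPU training on
synthetic cohorts — the smaller networks tolerate and need the larger
rate. These are stand-in architectures that preserve the input/output and
training contracts of the published models, not re-implementations of them;
parameter counts stay below two million.

## What the phantom generator emulates — and what it does not

`phantom_spec()` / `generate_cohort()` produce co-registered cases: an
ellipsoidal prostate whose semi-axes scale with the field of view,
randomly oriented ellipsoidal lesions (default semi-axes 4.5–7 mm, i.e.
volumes of roughly 0.4–1.4 cm^3, so every planted lesion clears the
250 mm^3 filter), per-voxel grade assignment with a contiguous aggressive
component occupying a drawn fraction of the lesion (30% of lesions are pure
Gleason-pattern-3 by default, the rest draw an aggressive fraction from
0.2–0.8), and T2w/ADC volumes in which lesions appear as smoothed,
noisy signal drops. Lesions are placed with at least 5 mm surface
separation so they remain distinct components after closing.

The simulated radiologist misses each lesion with probability 0.2 (the
reported fraction of MRI-invisible or hardly visible tumors), shrinks
outlines in-plane about each slice centroid by a linear factor of 0.87, and
skips individual lesion slices with probability 0.1; together these make
outline volumes average about 68% of the true lesion volume, matching the
reported aggregate under-estimation. Because only the aggregate ratio is
known, the split between in-plane shrinkage and slice skipping is a package
choice, exposed in the spec. In-plane geometric scaling was chosen over
erosion iterations because erosion steps are too coarse to hit a volume
ratio for thin lesions at 3–4.2 mm slice spacing, while sub-pixel in-plane
scaling resolves it smoothly at any lesion size. The simulated pathologist
outlines full extent on each annotated slice and skips slices with
probability 0.1, carrying no grade information.

Not emulated: MRI physics (no b-values, no ADC computation from DWI),
registration error between modalities or between MRI and histopathology
(synthetic data are born co-registered; the registration platforms used for
real data are outside this package's scope), anatomic zonal structure,
multifocal satellite lesions below the filter, or inter-annotator
variability beyond the parametric model above. Passing tests therefore
certify the label-derivation and evaluation machinery and the direction of
label-quality effects under controlled degradation — not clinical
performance on real cohorts, whose headline metrics depend on registration
quality and full-scale training.

## Numerical choices

* Morphology is computed by FFT convolution; closing runs on a canvas
  padded by the kernel extent, making it exactly the closing of the voxel
  set in an unbounded grid (extensive everywhere, including image borders).
  Thresholds 0.5 below the count protect against floating-point jitter.
* Connected components use an adjacency graph over foreground voxels
  (26-connectivity by default, configurable to 6); the test suite checks
  equality with an independent flood fill.
* Note that closing only bridges gaps between structures at least as thick
  as the structuring element: two isolated voxels a pixel apart are *not*
  merged — this is a property of mathematical closing, not an
  implementation detail.
* Argmax ties go to the earlier class (normal before indolent before
  aggressive), making hard labels deterministic.
* Volumes are indexed `[x, y, z]`, 1-based; "left" defaults to low image x
  with a `laterality` flag on the sextant partition.
* All randomness flows from explicit seeds through a splittable per-case
  scheme (case seeds are independent of cohort size, so cohorts can be
  extended without reshuffling), and every generator restores the caller's
  RNG state.
* Per-voxel class probabilities must sum to 1 within 1e-4 wherever scored;
  constant-intensity volumes are rejected by normalization rather than
  producing NaNs; a NaN training loss aborts with diagnostics.

## Problem sizes

The package's own experiments (test suite and `scripts/acceptance.R`) run
on a 64 x 64 x 12 grid at 1 mm pixels and 3 mm spacing — the same gland
and lesion geometry in millimetres as the full 224 x 224 / 0.29 mm
analysis grid, at desk-scale cost. Cohort sizes: 50 cases for annotator
calibration, 30 for label concordance, 20 for planted-class recovery, and
12 training / 6 test cases, 3 epochs, 3 seeds for the supervision-ordering
experiment. These sizes are the package's reference experiment; the same
functions run unchanged at the full grid.

## Known limitations

* The biopsy-style confirmation error model (adjacent-category flips at a
  configurable rate) reproduces only the *existence* of confirmation error,
  not any empirical error structure.
* Histogram intensity standardization implements decile landmark mapping;
  scanner-specific standardization recipes vary, and both implemented
  methods are approximations.
* The desk-scale networks demonstrate ordering effects between label
  strategies; their absolute metrics are not comparable to full-scale GPU
  training.
* Lesion-level ROC analysis uses the sextant convention throughout; no
  FROC, voxel-level AUC, or calibration analysis is provided.
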