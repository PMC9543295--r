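# prostlab

Comparing ground-truth labeling strategies for machine-learning lesion
detection on prostate MRI.

## The problem

Deep-learning "digital radiologists" that detect and grade prostate cancer
on T2-weighted and ADC MRI need per-voxel training labels, and those labels
can come from sources of very different quality: radiologists outlining
suspicious lesions during clinical reads (who miss MRI-invisible tumors,
under-estimate extent and skip slices), pathologists outlining cancer on
whole-mount histopathology (full extent, but no grade and not on every
slice), or an automated Gleason-grading model — a *digital pathologist* —
whose dense per-pixel grade predictions are mapped onto MRI. Which labels
train the best models, and what does each label type cost you at evaluation
time? `prostlab` implements the complete comparison methodology, exercised
end-to-end on seeded synthetic phantoms with known ground truth.

## What's in the box

* **Four label strategies** on a common coded grid (0 outside, 1 normal,
  2 indolent = Gleason pattern 3, 3 aggressive = pattern 4+):
  `LRad` (pathology-confirmed radiologist outlines), `LPath` (pathologist
  outlines graded by the digital pathologist), `LLesionDPath` (lesion-level
  digital-pathologist labels) and `LPixelDPath` (pixel-level labels that
  keep the aggressive/indolent mixture inside lesions).
* **Lesion formation**: morphological closing with a 3D structuring element
  of stacked in-plane disks (radii 0.5, 1.5, 0.5 mm) plus connected-component
  labeling; lesion volume `LV = PSx x PSy x Dz x NL`; lesions under
  250 mm^3 discarded; classification by the 1% rule (>= 1% aggressive
  voxels -> aggressive, else >= 1% indolent -> indolent, else benign) or by
  targeted-biopsy grade group (>= 2 aggressive, 1 indolent, benign normal).
* **Sextant-based lesion-level evaluation**: positives are ground-truth
  lesions, negatives are lesion-free sextants (left/right x base/mid/apex);
  rank ROC-AUC, Dice, sensitivity, specificity per patient, aggregated as
  mean +/- population SD; 4 x 4 cross-label train/eval matrices.
* **Desk-scale digital radiologists**: small 2.5D encoder-decoder CNNs
  (spcnet-, unet-, branched-unet- and 2D deeplab-like variants) trained with
  class-balanced cross-entropy over prostate voxels, Adam, case-level
  cross-validation folds; deterministic under a seed, pure R.
* **Synthetic phantom cohorts**: co-registered T2w/ADC ellipsoid phantoms
  with planted graded lesions and imperfect human annotators (radiologists
  miss ~20% of lesions and outline ~68% of true volume; pathologists skip
  slices), NIfTI + JSON manifest I/O, YAML-configurable specs.

## Worked example

```r
library(prostlab)

spec <- phantom_spec(grid_x = 64, grid_y = 64, n_slices = 12,
                     pixel_size_mm = 1.0, lesion_radius_range_mm = c(4.5, 6),
                     seed = 42)
cohort <- generate_cohort(spec, 6)
labels <- derive_cohort_labels(cohort)

labels$LLesionDPath$case_001$lesion_set$table
#>   lesion_id  NL volume_mm3 n_aggressive n_indolent      class kept
#> 1         1 159        477           72         87 aggressive TRUE
#> 2         2 169        507           61        108 aggressive TRUE

run_label_concordance(cohort, labels, tasks = "cancer")
#> <concordance_report>
#>   task cancer, mean Dice (pred x truth):
#>               truth_label
#> pred_label     LLesionDPath LPath LPixelDPath  LRad
#>   LLesionDPath        1.000 0.976       1.000 0.497
#>   LPath               0.976 1.000       0.976 0.497
#>   LPixelDPath         1.000 0.976       1.000 0.497
#>   LRad                0.497 0.497       0.497 1.000
```

Every planted lesion here clears the 250 mm^3 filter and carries its grade
composition (`n_aggressive` / `n_indolent` voxels inside the closed lesion);
both lesions are aggressive under the 1% rule. The concordance matrix shows
the central effect the package studies: the degraded radiologist labels
(`LRad`) overlap the pathologist labels at Dice ~ 0.50 on this cohort, while
digital-pathologist labels agree with them at Dice ~ 0.98 — so models
trained on the former inherit a handicap that the sextant-based evaluation
then quantifies (`fit_digital_radiologist()`, `predict()`,
`evaluate_patient()`, `cross_label_matrix()`, or everything at once via
`run_study()`).

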