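Package: prostlab
Title: Labeling Strategies for Prostate MRI Lesion Detection Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing ground-truth labeling strategies for
    machine-learning lesion detection on prostate MRI. Implements four label
    types derived from per-voxel histologic grade maps and human outlines
    (pathology-confirmed radiologist outlines, pathologist cancer outlines,
    and lesion-level and pixel-level labels from an automated Gleason
    grading model), 3D morphological lesion formation with volume filtering,
    sextant-based lesion-level evaluation (ROC-AUC, Dice, sensitivity,
    specificity), small trainable multi-class segmentation models, and a
    seeded synthetic phantom generator of co-registered T2-weighted and
    apparent-diffusion-coefficient volumes with imperfect human-annotation
    simulators for end-to-end study of label concordance and cross-label
    model evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
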