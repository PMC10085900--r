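---
title: "Slice-wise detection and 3D localization of the sternoclavicular joint region in CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-wise detection and 3D localization of the sternoclavicular joint region in CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clavloc)
```

## The problem

Forensic age assessment of adolescents and young adults relies heavily on the
ossification stage of the medial clavicular epiphyseal cartilages — the last
growth plates in the body to fuse. Training diagnostic networks on this
structure requires cropping CT volumes to the relevant region, which in turn
requires knowing where that region is. `clavloc` automates that localization:
it treats the sternoclavicular joint region (sternum plus medial clavicles, a
large and easy-to-identify proxy for the growth plates themselves) as a
single-class object-detection target in axial CT slices, and reduces the
per-slice detections of a whole volume to one `(x, y, slice)` location
estimate per scan.

The method has three stages:

1. **Per-slice preprocessing.** Voxel values are clipped to the window
   [-200, 600] HU — wide enough to keep bone and the surrounding soft tissue
   informative while discarding extreme densities — then each axial slice is
   resized to a square raster and linearly rescaled into [0, 1].
2. **Slice-wise 2D detection.** A one-stage anchor-based detector with a
   sigmoid classification head trained under focal loss and a smooth-L1
   box-regression head scores dense candidate boxes on every slice.
   Detections with classification score ≥ 0.05 are positive; greedy NMS at
   IoU 0.5 removes duplicates.
3. **Max-score aggregation.** All positive detections of a scan are pooled
   and the single highest-scoring detection wins; its box center and slice
   index are the scan's unique location estimate. The rule is a pure argmax —
   no smoothing across slices, no 3D NMS.

## The detector

No deep-learning framework is assumed: the package implements its compact
detector directly in R. The backbone is three 3×3-convolution + ReLU +
2×2-max-pool stages (default 16/32/48 channels), giving a stride-8 feature
grid; on each grid cell a classification head scores one anchor per
(size, aspect-ratio) pair and a regression head predicts the standard
center-offset/log-scale box encoding. Convolutions are evaluated as shifted
BLAS matrix products, and backpropagation is hand-derived (it is verified
against finite differences in the development history). Training uses Adam,
random flip augmentation (probability 0.5, axis chosen at random, image and
box flipped together), and a plateau schedule that divides the learning rate
by `lr_decay_factor` whenever the monitored loss fails to improve for
`plateau_patience` consecutive epochs.

This compact architecture deliberately trades capacity for CPU-scale
trainability; the pipeline around it is detector-agnostic. The
`predict_boxes()` generic is the adapter seam: any full-scale detector
(e.g. a pretrained RetinaNet served from another process) can be wrapped in
an object implementing that one method and used unchanged by
`detect_volume()`, `estimate_location()` and the evaluation stack.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `hu_min`, `hu_max` | -200, 600 HU | clinical preprocessing window |
| `target_size` / `input_size` | 512 px (clinical), 64 px (phantom) | square raster side |
| `score_threshold` | 0.05 | positive-detection score cut-off |
| `nms_iou` | 0.5 | NMS overlap threshold |
| `focal_alpha`, `focal_gamma` | 0.25, 2 | focal-loss weighting/focusing |
| `epochs`, `base_lr` | 20, 1e-5 (clinical); 10, 2e-3 (`mini_detector_config()`) | training schedule |
| `plateau_patience`, `lr_decay_factor` | 3, 10 | learning-rate plateau schedule |

The clinical-protocol learning rate of 1e-5 suits fine-tuning a pretrained
backbone; a compact net trained from random initialization needs a far larger
step, hence the 2e-3 of `mini_detector_config()`. The classification head's
bias is initialized to the focal prior (π = 0.01), so an untrained detector
scores every anchor near 0.01 — below the positive threshold — which both
stabilizes early focal-loss training and makes "untrained ⇒ no detections" a
testable contract.

Design choices where the protocol is genuinely open: the plateau scheduler
monitors the *training* loss by default (configurable to validation loss);
the final-epoch weights are used with no early stopping or model selection;
box regression uses smooth-L1 on anchor offsets; every anchor surviving NMS
remains a separate detection; predicted probabilities are clamped at 1e-7
from the interval boundaries before taking logs.

## Evaluation protocol

Per-slice outcomes follow the positive/match rules: a positive detection
(score ≥ 0.05) matches when its IoU with the slice's ground-truth box exceeds
0.5 and the class agrees. A slice is TP (annotated, matched), FN (annotated,
no positive detection), TN (unannotated, no positive detection) or FP
(a positive detection with no match — on annotated *or* unannotated slices).
Because a positive-but-poorly-overlapping detection on an annotated slice is
an FP under the per-detection rule, the report's presence/absence table
re-partitions slices by annotation status (annotated: matched vs not;
unannotated: positively detected vs not) so that its row totals equal the
numbers of annotated and unannotated slices. Both views are reported; the
raw outcome counts and the table disagree only on that one corner case.

Average precision is the VOC-style all-point interpolated area under the
precision-recall curve over score-ranked detections, with greedy one-to-one
matching in descending score order (each ground truth matched at most once,
duplicates are false positives). The test suite pits this implementation
against an independent brute-force oracle that enumerates the cumulative
precision-recall table and takes max-right precision.

Per-scan localization has three categories — TP (estimate in an annotated
slice, box matched at IoU > 0.5), FP (anything else with an estimate), FN
(no estimate at all; every scan contains the target, so there are no true
negatives). For FP scans the distance is measured to the ground-truth box
center on the *nearest annotated slice* (nearest by absolute slice
difference, ties to the lower index); the signed slice offset is reported
alongside the in-plane Euclidean distance, both in pixels on the
preprocessed raster. Median/quartile summaries use linear interpolation
between order statistics (R's default quantile type 7).

## The phantom generator

Clinical CT with expert annotations cannot ship with a package, so every
stage is exercised on synthetic phantoms. A phantom volume is an air
background (-1000 HU) holding an elliptical soft-tissue body; the target —
two lateral "clavicle" lobes meeting a central "sternum" block, drawn at
bone density (300-1000 HU) — occupies a run of consecutive slices in the
anterior upper body, tapering slightly toward the ends of its span. A
posterior "spine" column appears on *every* slice and a peripheral bone
shell rings the body, so brightness alone cannot solve the task: the
detector must learn the target's shape and position. Gaussian HU noise
(sd 20) covers everything. Each target slice carries one tight ground-truth
box; boxes are stored on the original raster and rescaled analytically.

Default conditions: 40 slices of 128×128 px per volume with a 4-slice
target span (10% of slices annotated), detector input 64×64. Clinical
chest CT has ~300 slices and ~1.5% annotated; emulating that sparsity at
package scale would inflate training volumes 7-fold for no change in the
learning problem's structure, so the 40-slice volume is the package's
chosen problem size. The headline self-check trains on 40 phantom volumes
(plus 5 for validation), evaluates on 12 held-out volumes (480 slices), and
requires per-slice AP ≥ 0.90 with ≥ 90% of held-out scans localized to an
annotated or directly adjacent slice — the phantom-scale analogue of
clinical behavior where nearly all scans are correct and the rare misses
are off by a single slice. Determinism is checked by reproducing a training
history and evaluation report bit-for-bit from the same seed.

What phantom success does *not* show: robustness to anatomical variation,
pathology, metal artifacts, varying slice thickness, or scanner protocol
differences; the phantom's target is geometrically stereotyped and its
distractors are crude. Phantom results validate the pipeline's mechanics
and the method's logic, not clinical performance.

## Numerical and degenerate-input choices

* A constant slice normalizes to all zeros (the "no signal" reading of the
  min = max case).
* Non-square slices are stretched to the square target; annotations are
  rescaled analytically via the returned `(scale_x, scale_y)`, never
  redrawn.
* Normalization uses each slice's own post-clip extrema; when the window
  endpoints occur in the slice this coincides with fixed-window scaling.
* Exactly tied classification scores break deterministically (lowest slice,
  then lowest box x, then y), so aggregation is independent of detection
  order.
* Decoded log-scale box offsets are capped at 4 to keep `exp()` bounded for
  untrained heads; boxes are clipped to the raster.
* `floor(0.9 × n)` scans form a training split; splits operate on whole
  scans only, so no scan leaks across subsets.

## Limitations

* Volumetric input is NIfTI only; DICOM series must be converted upstream
  (no DICOM reader is available to the package).
* The compact detector is single-scale and single-class; it is not a
  substitute for a full feature-pyramid detector on 512×512 clinical data —
  for that, wrap an external model via `predict_boxes()`.
* Left/right sternoclavicular joints are not distinguished; the target is
  the merged region containing both.
* No slice-thickness resampling: slice indices are acquisition indices.

## A complete run

```{r, eval = FALSE}
cfg <- run_config(out_dir = "run1", seed = 7, n_volumes = 50)
report <- run_pipeline(cfg)
print(report)
```

The run directory then holds `weights.rds`, `history.csv`,
`predictions.csv`, `report.json` and `manifest.json`; the manifest records
every threshold actually used (score 0.05, IoU 0.5, HU window) so a run can
be audited after the fact.
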