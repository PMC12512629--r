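---
title: "Tiled two-stage detection of white spot lesions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiled two-stage detection of white spot lesions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WSLTiles)
```

## The problem

White spot lesions (WSLs) are pre-cavitation enamel demineralizations —
opaque white patches, most common in orthodontic patients, concentrated in
the peri-gingival band of the tooth surface. On a frontal intra-oral
photograph of roughly 4000 × 3000 pixels, a typical WSL bounding box has an
area of a few thousand pixels: a 54 × 54 px patch on a 12-megapixel canvas.
Standard detector preprocessing resizes the whole image to fit a 640 × 640
square, which multiplies every box area by `0.16² ≈ 0.026` and pushes the
typical lesion below the COCO "small object" boundary of 1024 px (32²),
where detectors of every family perform worst. That is the failure mode
this package addresses.

## The tiled two-stage procedure

`twDetect()` implements the inference procedure around which the package is
built:

1. **Proportional resize.** The photograph is isotropically scaled by
   `min(fit/width, fit/height)` to fit a `fit` × `fit` square (default
   640), with no padding (`proportionalResize()`).
2. **Tooth stage.** A fast tooth detector runs on the resized image;
   greedy NMS (default IoU threshold 0.5) removes duplicate tooth boxes.
3. **Union crop.** Tooth boxes are lifted back to the original frame
   (inverse rescale, half-up integer rounding) and their bounding
   rectangle — optionally expanded by a margin, default 0 — is cut from
   the *full-resolution* image (`unionCrop()`). If the tooth stage finds
   nothing, the full image serves as the crop; the fallback is flagged.
4. **Tiling.** The crop is covered with `window` × `window` tiles
   (default 640) whose offsets advance by `window − overlap` (default
   overlap 50 px); when the last regular tile misses the crop edge, a
   final tile clamped at `dim − window` is appended (`tileGrid()`). Tiles
   are cut at native resolution — no resampling.
5. **Lesion stage.** The lesion detector runs on every tile and, for a
   holistic view, on the entire crop proportionally resized to the fit
   square.
6. **Remap and merge.** Tile detections return to the original frame by
   exact integer translation; holistic detections by inverse rescale plus
   translation. A single pooled per-class NMS (default IoU 0.5) merges
   duplicates; output is sorted by descending confidence.

`baselineDetect()` is the comparison arm: resize the whole image, detect
once, NMS, inverse-rescale.

Both arms take *injected* detector backends satisfying a minimal contract
(`detect()`, optionally `activations()`), because the subject under test is
the slicing architecture, not any particular network. The bundled
`blobDetector()` — threshold, morphological opening, 8-connected
components, area filter — is deliberately classical plumbing that makes
every pipeline property testable without trained weights. Its confidence
(mean component saliency, capped at 1) is not a calibrated probability.

### Geometry conventions and numerical choices

* Boxes are 0-based, half-open `[xmin, xmax) × [ymin, ymax)` everywhere;
  YOLO-normalized centers are converted only at the I/O boundary. This
  removes off-by-one drift between the image, crop, tile and resized
  frames.
* All rescaling rounds half-up (`floor(x + 0.5)`); a box collapsed by
  rounding is widened to 1 px. A round trip that *starts in the coarser
  frame* reproduces coordinates within 1 px; starting at full resolution
  the error is bounded by `ceiling(1/scale)` px, which is why tile
  detections are remapped by pure translation rather than through the
  resized frame.
* NMS suppresses on strict `> threshold`, breaks confidence ties by input
  order, and is therefore bit-reproducible. The suppression thresholds are
  configuration (default 0.5 at both stages) since the source procedure
  specifies only that "significantly overlapping" boxes are eliminated.
* Tile containment guarantee: an object with max side ≤ `overlap` is
  wholly contained in at least one tile at any position (the containment
  windows of consecutive tiles are gapless precisely when the side is at
  most the overlap). Larger objects may be seen only piecewise by single
  tiles; duplicate and partial views are resolved by the final NMS, with
  no special border heuristics.

## Evaluation suite

All metrics work on per-image lists of box data.frames.

* **Pixel-wise Cohen's kappa** (`pixelKappa()`), the primary agreement
  metric: predicted and reference box sets are rasterized to binary masks
  at original resolution and the 2 × 2 pixel confusion matrix is pooled
  over the dataset before `κ = (p_o − p_e)/(1 − p_e)` is taken. Pooling
  (rather than averaging per-image kappas) matches a single dataset-level
  value and is stable for images without lesions; per-image averaging is
  available via `pooled = FALSE`. When both raters are constant the value
  is undefined and an error is raised rather than a silent 0.
* **AP@0.5 and mAP@0.5:0.95** (`apAt()`, `mapRange()`): greedy
  confidence-ordered one-to-one matching per image, dataset-pooled
  cumulative precision–recall, and COCO 101-point interpolation (mean over
  the recall grid 0, 0.01, …, 1 of the maximum precision at recall ≥ the
  grid point). The test suite checks this against an independent
  brute-force re-computation on randomized instances at 1e-6.
* **TP/FN/FP and F1** are cutoff-dependent; since no operating cutoff is
  prescribed for reported counts, they are reported at the confidence
  cutoff maximizing F1 at IoU 0.5 (`bestF1Cutoff()`), which is logged and
  configurable. `f1OverIou()` traces F1 across IoU thresholds at that
  fixed cutoff.
* **Confidence intervals**: nonparametric percentile bootstrap over images
  (`bootstrapCI()`, default 1000 resamples, seeded). No multiple-testing
  correction is applied anywhere; between-arm differences are reported
  with their intervals.
* No ROC/AUC is computed: true negatives are undefined for box detection.

For two-group comparisons of continuous quantities the package takes no
position beyond providing the bootstrap; where a rank test is wanted,
`stats::wilcox.test()` is the assumed non-parametric choice.

## Dataset-geometry analyses

`areaStats()` summarizes box areas with type-7 (linear interpolation)
quantiles — the printed IQRs this emulates cannot disambiguate the
convention, so one is fixed and documented — and counts COCO size classes
(small < 1024 px ≤ medium < 9216 px ≤ large). `downscaleShift()` applies a
resize transform's squared scale to the areas and recomputes the classes;
`chiSquare2x2()` (Pearson, no continuity correction, 1 df) tests the
small-vs-rest shift. `absoluteHeatmap()` accumulates boxes in the
normalized image frame; `relativeHeatmap()` assigns each lesion to the
tooth box of maximal intersection area — maximal IoU would be near zero for
every small lesion inside a large tooth — and accumulates it in the host
tooth's unit square. `crownCoverage()` reports the exact union area of
lesion boxes clipped to a tooth box over the tooth-box area (a
coordinate-compression sweep, not rasterization). All of these operate on
bounding boxes, the only geometry annotations provide: coverage of the
anatomical crown is approximated by box geometry, a stated limitation.

## Score-CAM

`scoreCam()` implements gradient-free class activation mapping against the
backend contract: each activation channel is min–max normalized (constant
channels become zero), bilinearly upsampled to image size, and used as a
multiplicative soft mask on all color channels; the target score of each
masked image is compared with the unmasked baseline; channel weights are
the softmax of the score increases; the CAM is the rectified weighted sum
of the upsampled maps. The target score is pluggable: a detection
confidence (`confidenceScore()`), the maximum IoU between detections on
the masked image and reference annotations (`iouScore()` — the
localization-oriented target), or any user function. Which layer's
channels are exposed is a backend concern. Gradient-based CAM variants are
out of scope: the contract provides no gradients.

## The synthetic generator: what it emulates, and what it does not

`generateDataset()` is first-class, tested code, not a fixture dump. It
emulates the *geometry and statistics* of frontal intra-oral photographs:

* canvas 4000 × 3000 px (test preset 1600 × 1200, with areas scaled by
  canvas area);
* two arch rows of 10 bright rounded tooth rectangles on a dark oral
  background with Gaussian pixel noise (sd 0.02);
* lesion count per image ~ Poisson(13), matching roughly thirteen
  annotated lesions per photograph in the emulated material;
* lesion box areas log-normal with median 2898 px at full scale and
  log-sd 0.731, fitted so the quartiles land near 1895 and 5080 px — the
  right-skew (median well below the IQR midpoint) is what makes the
  log-normal the natural family here; distinct lesions get disjoint boxes
  (coincident blobs would merge into one connected component and one
  annotation);
* a lesion's center falls in the outer 25% band of its host tooth's unit
  square with probability 0.8, weighted toward the gingival side (tooth
  top on the upper arch, bottom on the lower), with 60% of lesions on the
  upper arch.

Brightness contrasts (background ≈ 0.22, tooth ≈ 0.80, lesion ≈ 0.96 in
luma) are chosen so the bundled blob detector is near-perfect at native
resolution and degrades after downscaling — small lesions blur below its
threshold and area floor. This makes the tiled-vs-baseline comparison
meaningful *by construction*: it reproduces the direction of the effect
(tiling preserves small-object detectability), not any clinical magnitude.
What the generator does **not** emulate: real enamel texture, brackets and
appliances, specular highlights, lips/cheek retractors, camera optics, or
annotator disagreement. Passing tests therefore demonstrate the
correctness of the geometry, metrics and pipeline plumbing on data with
known truth — they are not evidence about photographs.

All randomness flows through the configured seed; the global RNG state is
saved and restored, and a fixed seed yields byte-identical label files.

## Problem sizes used by the test and reproduction runs

The bundled reproduction script (`scripts/acceptance.R`) and the
end-to-end test block run 50 images at the full 4000 × 3000 resolution
with generator defaults — large enough that both arms see ~600 lesions —
while unit and property tests use the 1600 × 1200 preset and randomized
small instances (1000 tile grids, 100+ metric scenarios). These sizes were
chosen to make the direction-of-effect comparisons stable across seeds
while keeping a full run in the minutes range on one core.

## Known limitations

* The blob reference detector is not a lesion detector for real
  photographs; plugging in a trained network behind the `detect()`
  contract is the intended path to clinical data.
* Crown coverage uses box geometry, which understates true crown area
  coverage when crowns are partly occluded and overstates lesion area
  (boxes vs. blobs).
* The pooled kappa treats every pixel as exchangeable; per-image
  weighting is available but equally conventional.
* Rotated boxes, soft-NMS, class-agnostic NMS, multi-scale tile pyramids
  and any training functionality are out of scope.
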