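# The tiled two-stage inference procedure and the whole-image-resize
# baseline arm it is compared against. Both take injected detector
# backends, so any detector honoring the contract (including a real
# network wrapper) can be plugged in without touching this code.

#' Pipeline configuration
#'
#' @param fit side of the fitting square for proportional resizing (px).
#' @param window tile side (px).
#' @param overlap minimum overlap of adjacent tiles (px; must be < window).
#' @param cropMargin expansion of the tooth-union crop (px; default tight).
#' @param toothNms NMS IoU threshold for the tooth stage, in (0, 1).
#' @param finalNms NMS IoU threshold for the final merged lesion set.
#' @param confidenceFloor minimum confidence of reported detections.
#' @return a validated configuration list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(fit = 640L, window = 640L, overlap = 50L,
                           cropMargin = 0L, toothNms = 0.5, finalNms = 0.5,
                           confidenceFloor = 0) {
  stopifnot(fit > 0, window > overlap, overlap >= 0,
            toothNms > 0, toothNms < 1, finalNms > 0, finalNms < 1,
            cropMargin >= 0, confidenceFloor >= 0, confidenceFloor <= 1)
  structure(list(fit = as.integer(fit), window = as.integer(window),
                 overlap = as.integer(overlap),
                 cropMargin = as.integer(cropMargin),
                 toothNms = toothNms, finalNms = finalNms,
                 confidenceFloor = confidenceFloor),
            class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat(sprintf(paste0("PipelineConfig: fit %d, window %d, overlap %d, ",
                     "crop margin %d, NMS tooth %.2f / final %.2f, ",
                     "confidence floor %.2f\n"),
              x$fit, x$window, x$overlap, x$cropMargin, x$toothNms,
              x$finalNms, x$confidenceFloor))
  invisible(x)
}

.finalizeDetections <- function(dets, threshold, floor.) {
  if (nrow(dets)) {
    dets <- do.call(rbind, lapply(split(dets, dets$label), nms,
                                  iouThreshold = threshold))
    dets <- dets[dets$confidence >= floor., , drop = FALSE]
    dets <- dets[order(-dets$confidence), , drop = FALSE]
    rownames(dets) <- NULL
  }
  dets
}

#' Tiled two-stage detection
#'
#' Runs the full tooth-to-lesion procedure on one image: (1) proportional
#' resize to the fit square; (2) tooth detection on the resized image,
#' followed by NMS; (3) tooth boxes lifted back to the original frame and
#' their union (plus margin) cropped from the full-resolution image;
#' (4) the crop is scanned with overlapping windows and the lesion
#' detector runs on every tile at native resolution and, holistically, on
#' the whole crop proportionally resized to the fit square; (5) all lesion
#' boxes are remapped to the original frame (tiles by exact translation,
#' the holistic pass by inverse rescale plus translation) and merged by a
#' final per-class NMS. When the tooth stage finds nothing the full image
#' is used as the crop (fallback, flagged in the result attributes).
#'
#' @param image image or numeric array (x first), values in \[0, 1\].
#' @param toothDetector,lesionDetector backends honoring the [detect()]
#'   contract.
#' @param config a [pipelineConfig()].
#' @return detection data.frame in the original frame, sorted by
#'   descending confidence, with attributes `crop` (the crop box),
#'   `grid` (the [TileGrid-class]), `fallback` (logical), and
#'   `toothDetections`.
#' @export
twDetect <- function(image, toothDetector, lesionDetector,
                     config = pipelineConfig()) {
  sz <- .imageSize(image)
  rt <- proportionalResize(sz[1], sz[2], config$fit)
  resized <- resizeImage(image, rt)

  teeth <- detect(toothDetector, resized)
  teeth <- if (nrow(teeth)) nms(teeth, config$toothNms) else teeth
  fallback <- nrow(teeth) == 0L
  if (fallback) {
    message("tooth stage found no teeth; falling back to the full image")
    crop <- wslBoxes(0, 0, sz[1], sz[2])
    teethOrig <- teeth
  } else {
    teethOrig <- rescaleBox(teeth, rt, "inverse")
    crop <- unionCrop(teethOrig, sz[1], sz[2], margin = config$cropMargin)
  }

  cw <- crop$xmax - crop$xmin
  ch <- crop$ymax - crop$ymin
  grid <- tileGrid(cw, ch, config$window, config$overlap)
  cropImg <- cropImage(image, crop)

  pooled <- list()
  offs <- tileOffsets(grid)  # row-major: per-tile detection order is logged
  for (i in seq_len(nrow(offs))) {
    tile <- cropImage(cropImg, wslBoxes(offs[i, 1], offs[i, 2],
                                        min(cw, offs[i, 1] + grid@tileSize[1]),
                                        min(ch, offs[i, 2] + grid@tileSize[2])))
    d <- detect(lesionDetector, tile)
    if (nrow(d))
      pooled[[length(pooled) + 1L]] <-
        toOriginal(d, offs[i, ], c(crop$xmin, crop$ymin))
  }
  # holistic pass on the whole crop, proportionally resized to the fit size
  hrt <- proportionalResize(cw, ch, config$fit)
  hd <- detect(lesionDetector, resizeImage(cropImg, hrt))
  if (nrow(hd))
    pooled[[length(pooled) + 1L]] <-
      toOriginal(rescaleBox(hd, hrt, "inverse"), c(0, 0),
                 c(crop$xmin, crop$ymin))

  dets <- if (length(pooled)) do.call(rbind, pooled) else
    wslBoxes(numeric(), numeric(), numeric(), numeric(),
             label = character(), confidence = numeric())
  dets <- .finalizeDetections(dets, config$finalNms, config$confidenceFloor)
  structure(dets, crop = crop, grid = grid, fallback = fallback,
            toothDetections = teethOrig)
}

#' Whole-image resize baseline detection
#'
#' The comparison arm: the full image is proportionally resized to the fit
#' square, the lesion detector runs once, NMS is applied, and boxes are
#' inverse-rescaled to the original frame (always inside the image
#' bounds). At the source material's ~4000 x 3000 resolution this pushes
#' median-sized lesions into the COCO small-object regime.
#'
#' @inheritParams twDetect
#' @param lesionDetector backend honoring the [detect()] contract.
#' @return detection data.frame in the original frame, sorted by
#'   descending confidence.
#' @export
baselineDetect <- function(image, lesionDetector, config = pipelineConfig()) {
  sz <- .imageSize(image)
  rt <- proportionalResize(sz[1], sz[2], config$fit)
  d <- detect(lesionDetector, resizeImage(image, rt))
  d <- .finalizeDetections(d, config$finalNms, config$confidenceFloor)
  if (nrow(d)) d <- rescaleBox(d, rt, "inverse")
  rownames(d) <- NULL
  d
}
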