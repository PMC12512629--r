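# Gradient-free score-CAM against the detector activations contract.
# Each activation channel, min-max normalized and bilinearly upsampled to
# image resolution, soft-masks the image; the change of a scalar target
# score relative to the unmasked baseline weights the channels through a
# softmax, and the CAM is the rectified weighted sum of the upsampled
# maps. The target score may be a detection confidence, the maximum IoU
# against reference annotations (the localization-oriented target), or
# any user-supplied function.

.normalizeMap <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] == 0) return(m * 0)  # all-constant (incl. all-zero) -> 0
  (m - rng[1]) / (rng[2] - rng[1])
}

.upsampleMap <- function(m, width, height) {
  if (all(dim(m) == c(width, height))) return(m)
  EBImage::imageData(EBImage::resize(EBImage::Image(m), w = width, h = height))
}

.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Target score: maximum detection confidence
#'
#' @param detector a backend honoring the [detect()] contract.
#' @return function mapping an image to the top confidence (0 if none).
#' @export
confidenceScore <- function(detector) {
  function(image) {
    d <- detect(detector, image)
    if (nrow(d)) max(d$confidence) else 0
  }
}

#' Target score: maximum IoU against reference annotations
#'
#' The localization-oriented target: how well the detector's boxes on the
#' (masked) image overlap the reference boxes.
#'
#' @param detector a backend honoring the [detect()] contract.
#' @param gtBoxes reference box data.frame in the presented image's frame.
#' @return function mapping an image to the maximum detection-vs-reference
#'   IoU (0 when either side is empty).
#' @export
iouScore <- function(detector, gtBoxes) {
  function(image) {
    d <- detect(detector, image)
    if (nrow(d) == 0L || is.null(gtBoxes) || nrow(gtBoxes) == 0L) return(0)
    max(iouMatrix(d, gtBoxes))
  }
}

#' Score-CAM saliency map
#'
#' For each activation channel of `backend`: min-max normalize (constant
#' channels map to all-zero), bilinearly upsample to the image size, mask
#' the image by elementwise product on every color channel, and evaluate
#' `scoreFun`. Channel weights are the softmax of the score increases over
#' the unmasked baseline; the CAM is the negative-clipped weighted sum of
#' the upsampled normalized maps, so it is 0 wherever all activations are 0
#' and non-negative everywhere.
#'
#' @param backend a backend exposing [activations()].
#' @param image image or numeric array (x first), values in \[0, 1\].
#' @param scoreFun function mapping an image to a finite scalar target
#'   score (see [confidenceScore()], [iouScore()]).
#' @return numeric matrix at the image's spatial resolution.
#' @export
scoreCam <- function(backend, image, scoreFun) {
  stopifnot(is.function(scoreFun))
  maps <- activations(backend, image)
  if (length(maps) < 1L) stop("backend exposed no activation channels")
  a <- .asImageArray(image)
  sz <- .imageSize(image)
  up <- lapply(maps, function(m)
    .upsampleMap(.normalizeMap(m), sz[1], sz[2]))
  baseline <- scoreFun(a)
  increases <- vapply(up, function(m) {
    masked <- if (length(dim(a)) == 2L) a * m else
      a * array(rep(m, dim(a)[3]), dim = dim(a))
    s <- scoreFun(masked)
    if (!is.finite(s)) stop("target score must be finite")
    s - baseline
  }, numeric(1))
  w <- .softmax(increases)
  cam <- matrix(0, sz[1], sz[2])
  for (k in seq_along(up)) cam <- cam + w[k] * up[[k]]
  pmax(cam, 0)
}

#' Overlay a CAM on its image for rendering
#'
#' Min-max scales the CAM, maps it through a blue-to-red color ramp, and
#' alpha-blends it onto the image. Cosmetic only.
#'
#' @param image image or numeric array (x first).
#' @param cam matrix from [scoreCam()].
#' @param alpha blend weight of the CAM layer (default 0.5).
#' @return an EBImage color `Image`.
#' @export
camOverlay <- function(image, cam, alpha = 0.5) {
  a <- .asImageArray(image)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  c01 <- .normalizeMap(cam)
  ramp <- array(0, dim = dim(a))
  ramp[, , 1] <- c01                 # red grows with attention
  ramp[, , 3] <- 1 - c01             # blue where attention is low
  out <- (1 - alpha) * a + alpha * ramp
  EBImage::Image(pmin(pmax(out, 0), 1), colormode = EBImage::Color)
}
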