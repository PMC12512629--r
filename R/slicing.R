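# Pure geometry of the tiled two-stage pipeline: proportional resize,
# tooth-union crop, overlapping tile grid, and translation/rescale
# remapping between frames. Crops and tiles are taken at native resolution,
# so tile-to-original remapping is an exact integer translation.

#' Proportional resize to fit within a square
#'
#' Computes the single isotropic scale `min(fit / width, fit / height)`
#' that fits an image inside a `fit` x `fit` square while preserving the
#' aspect ratio. No padding: the target canvas is the scaled rectangle
#' itself, with dimensions rounded half-up. Upscaling is permitted when
#' both dimensions are below `fit`.
#'
#' @param width,height source dimensions in pixels (> 0).
#' @param fit side of the fitting square in pixels (default 640).
#' @return a [ResizeTransform-class].
#' @examples
#' proportionalResize(4000, 3000, 640)  # scale 0.16, target 640 x 480
#' @export
proportionalResize <- function(width, height, fit = 640L) {
  if (width <= 0 || height <= 0 || fit <= 0)
    stop("width, height and fit must be positive")
  scale <- min(fit / width, fit / height)
  target <- as.integer(roundHalfUp(c(width, height) * scale))
  new("ResizeTransform", scale = scale,
      sourceSize = as.integer(c(width, height)), targetSize = target)
}

setMethod("show", "ResizeTransform", function(object) {
  cat(sprintf("ResizeTransform %dx%d -> %dx%d (scale %.6g)\n",
              object@sourceSize[1], object@sourceSize[2],
              object@targetSize[1], object@targetSize[2], object@scale))
})

#' Rescale a box between the frames of a resize transform
#'
#' Multiplies (forward: source frame to target frame) or divides (inverse)
#' the coordinates by the transform's scale, rounds half-up to integer
#' pixels, and clips to the destination frame. A box that would collapse
#' under rounding is widened to 1 px. The forward-then-inverse round trip
#' reproduces each coordinate within `ceiling(1 / scale)` px (1 px when
#' `scale >= 1`).
#'
#' @param boxes box data.frame.
#' @param transform a [ResizeTransform-class].
#' @param direction `"forward"` (source -> target) or `"inverse"`.
#' @return the rescaled box data.frame (other columns preserved).
#' @examples
#' rt <- proportionalResize(4000, 3000, 640)
#' rescaleBox(wslBoxes(16, 80, 100, 200), rt, "inverse")  # [100,500,625,1250]
#' @export
rescaleBox <- function(boxes, transform, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  validateBoxes(boxes)
  if (nrow(boxes) == 0L) return(boxes)
  s <- if (direction == "forward") transform@scale else 1 / transform@scale
  frame <- if (direction == "forward") transform@targetSize else
    transform@sourceSize
  out <- boxes
  for (col in c("xmin", "ymin", "xmax", "ymax"))
    out[[col]] <- roundHalfUp(boxes[[col]] * s)
  # clip to frame, then restore >= 1 px extent for boxes collapsed by rounding
  out$xmin <- pmax(out$xmin, 0); out$ymin <- pmax(out$ymin, 0)
  out$xmax <- pmin(out$xmax, frame[1]); out$ymax <- pmin(out$ymax, frame[2])
  grow <- function(lo, hi, lim) {
    bad <- hi <= lo
    hi[bad] <- pmin(lo[bad] + 1, lim)
    lo[bad] <- hi[bad] - 1
    list(lo = lo, hi = hi)
  }
  gx <- grow(out$xmin, out$xmax, frame[1])
  gy <- grow(out$ymin, out$ymax, frame[2])
  out$xmin <- gx$lo; out$xmax <- gx$hi; out$ymin <- gy$lo; out$ymax <- gy$hi
  out
}

#' Minimal crop containing all tooth boxes
#'
#' The tight axis-aligned union rectangle of the tooth boxes, expanded by
#' `margin` on every side and clipped to the image bounds. This is the
#' region subsequently tiled at full resolution.
#'
#' @param toothBoxes box data.frame in the original frame (>= 1 row).
#' @param width,height image dimensions in pixels.
#' @param margin expansion in pixels (default 0: tight union).
#' @return a one-row box data.frame.
#' @export
unionCrop <- function(toothBoxes, width, height, margin = 0) {
  validateBoxes(toothBoxes)
  if (nrow(toothBoxes) == 0L)
    stop("unionCrop needs at least one tooth box")
  wslBoxes(max(0, min(toothBoxes$xmin) - margin),
           max(0, min(toothBoxes$ymin) - margin),
           min(width, max(toothBoxes$xmax) + margin),
           min(height, max(toothBoxes$ymax) + margin))
}

.axisOffsets <- function(dim, window, stride) {
  if (dim <= window) return(0L)
  off <- seq.int(0L, dim - window, by = stride)
  if (off[length(off)] + window < dim) off <- c(off, dim - window)
  as.integer(off)
}

#' Overlapping tile grid over a crop
#'
#' Per axis, offsets advance from 0 by `stride = window - overlap` while
#' the tile fits; if the last regular tile does not reach the crop edge, a
#' final tile clamped at `dim - window` is appended. Axes shorter than the
#' window get a single full-extent tile. Consequently every crop pixel is
#' covered, all tiles lie inside the crop, and with >= 2 tiles along an
#' axis consecutive tiles overlap by at least `overlap` pixels.
#'
#' @param cropWidth,cropHeight crop dimensions in pixels.
#' @param window tile side in pixels (default 640).
#' @param overlap minimum overlap of adjacent tiles in pixels (default 50).
#' @return a [TileGrid-class]; offsets are row-major (x fastest).
#' @examples
#' tileGrid(1300, 700)  # x offsets 0, 590, 660; y offsets 0, 60
#' @export
tileGrid <- function(cropWidth, cropHeight, window = 640L, overlap = 50L) {
  if (overlap < 0 || window <= overlap)
    stop("need window > overlap >= 0")
  stride <- as.integer(window - overlap)
  xs <- .axisOffsets(as.integer(cropWidth), as.integer(window), stride)
  ys <- .axisOffsets(as.integer(cropHeight), as.integer(window), stride)
  offsets <- cbind(x = rep(xs, times = length(ys)),
                   y = rep(ys, each = length(xs)))
  new("TileGrid", window = as.integer(window), overlap = as.integer(overlap),
      stride = stride, offsets = offsets,
      tileSize = as.integer(pmin(window, c(cropWidth, cropHeight))),
      cropSize = as.integer(c(cropWidth, cropHeight)))
}

#' @rdname tileOffsets
#' @export
setMethod("tileOffsets", "TileGrid", function(object) object@offsets)

setMethod("show", "TileGrid", function(object) {
  cat(sprintf(
    "TileGrid: %d tile(s) of %dx%d over %dx%d crop (stride %d, overlap %d)\n",
    nrow(object@offsets), object@tileSize[1], object@tileSize[2],
    object@cropSize[1], object@cropSize[2], object@stride, object@overlap))
})

#' Map a box from tile frame back to the original frame
#'
#' Tiles are cut from the crop at native resolution, so the mapping is an
#' exact integer translation by the tile origin followed by the crop
#' origin. With `tileOrigin = c(0, 0)` this maps crop-frame boxes.
#'
#' @param boxes box data.frame in the tile frame.
#' @param tileOrigin `c(x, y)` tile origin in the crop frame.
#' @param cropOrigin `c(x, y)` crop origin in the original frame.
#' @return the translated box data.frame.
#' @examples
#' toOriginal(wslBoxes(10, 10, 20, 20), c(590, 0), c(100, 500))
#' @export
toOriginal <- function(boxes, tileOrigin = c(0, 0), cropOrigin = c(0, 0)) {
  validateBoxes(boxes)
  dx <- tileOrigin[1] + cropOrigin[1]
  dy <- tileOrigin[2] + cropOrigin[2]
  boxes$xmin <- boxes$xmin + dx; boxes$xmax <- boxes$xmax + dx
  boxes$ymin <- boxes$ymin + dy; boxes$ymax <- boxes$ymax + dy
  boxes
}
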