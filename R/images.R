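# Raster convention: images are EBImage Image objects (or plain numeric
# arrays) with x along the first dimension, values in [0, 1]; pixel (x, y)
# in 0-based box coordinates is element [x + 1, y + 1].

#' @importFrom EBImage Image resize readImage writeImage bwlabel opening
#'   makeBrush colorMode Grayscale Color imageData
NULL

.asImageArray <- function(image) {
  a <- if (is(image, "Image")) EBImage::imageData(image) else image
  if (!is.numeric(a) || length(dim(a)) < 2L)
    stop("image must be a numeric array with x as the first dimension")
  a
}

.imageSize <- function(image) {
  d <- dim(.asImageArray(image))
  c(width = d[1], height = d[2])
}

.saliencyMap <- function(image, channelWeights) {
  a <- .asImageArray(image)
  if (length(dim(a)) == 2L) return(pmin(pmax(a, 0), 1))
  w <- channelWeights / sum(channelWeights)
  s <- a[, , 1] * w[1]
  for (k in 2:min(dim(a)[3], 3L)) s <- s + a[, , k] * w[k]
  pmin(pmax(s, 0), 1)
}

#' Cut a sub-image given a box
#'
#' @param image image or numeric array (x first).
#' @param box one-row box data.frame with integer coordinates.
#' @return the cropped array (same number of channels).
#' @export
cropImage <- function(image, box) {
  a <- .asImageArray(image)
  xs <- (box$xmin[1] + 1):box$xmax[1]
  ys <- (box$ymin[1] + 1):box$ymax[1]
  if (length(dim(a)) == 2L) a[xs, ys, drop = FALSE] else a[xs, ys, , drop = FALSE]
}

#' Resize an image to a transform's target frame
#'
#' Bilinear resampling (EBImage) to `targetSize`; `scale = 1` with matching
#' frames returns the input unchanged.
#'
#' @param image image or numeric array (x first).
#' @param transform a [ResizeTransform-class].
#' @return the resized array.
#' @export
resizeImage <- function(image, transform) {
  a <- .asImageArray(image)
  if (all(dim(a)[1:2] == transform@targetSize)) return(a)
  EBImage::imageData(EBImage::resize(EBImage::Image(a,
    colormode = if (length(dim(a)) == 2L) EBImage::Grayscale else EBImage::Color),
    w = transform@targetSize[1], h = transform@targetSize[2]))
}

#' Rasterize a set of boxes into a binary mask
#'
#' Marks every pixel whose unit cell intersects a box interior: columns
#' `floor(xmin)+1 .. ceiling(xmax)` clipped to the frame (exact for
#' integer-coordinate boxes under the half-open convention).
#'
#' @param boxes box data.frame in the frame's coordinates.
#' @param width,height frame dimensions in pixels.
#' @return logical `width` x `height` matrix.
#' @export
rasterizeBoxes <- function(boxes, width, height) {
  m <- matrix(FALSE, width, height)
  if (is.null(boxes) || nrow(boxes) == 0L) return(m)
  for (i in seq_len(nrow(boxes))) {
    xs <- max(1, floor(boxes$xmin[i]) + 1):min(width, ceiling(boxes$xmax[i]))
    ys <- max(1, floor(boxes$ymin[i]) + 1):min(height, ceiling(boxes$ymax[i]))
    if (length(xs) && length(ys)) m[xs, ys] <- TRUE
  }
  m
}
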