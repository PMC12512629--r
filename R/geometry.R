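# Shared coordinate convention: pixel boxes are 0-based, half-open
# [xmin, xmax) x [ymin, ymax), so area = (xmax - xmin) * (ymax - ymin) and a
# box lies inside a W x H frame iff xmin >= 0 and xmax <= W (same for y).
# YOLO-normalized centers are converted at the I/O boundary only.

#' Build a box/detection data.frame
#'
#' Boxes travel through the package as plain data.frames with columns
#' `xmin`, `ymin`, `xmax`, `ymax` and optionally `label` and `confidence`
#' (a detection). Coordinates are 0-based half-open pixels in whatever
#' frame the caller is working in.
#'
#' @param xmin,ymin,xmax,ymax numeric vectors of equal length.
#' @param label optional class labels (recycled).
#' @param confidence optional confidences in \[0, 1\] (recycled).
#' @return a validated box data.frame.
#' @examples
#' wslBoxes(0, 0, 10, 10, label = "wsl", confidence = 0.9)
#' @export
wslBoxes <- function(xmin, ymin, xmax, ymax, label = NULL, confidence = NULL) {
  df <- data.frame(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                   xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  if (!is.null(label)) df$label <- rep_len(as.character(label), nrow(df))
  if (!is.null(confidence)) {
    df$confidence <- rep_len(as.numeric(confidence), nrow(df))
  }
  validateBoxes(df)
  df
}

#' Validate a box data.frame
#'
#' Checks strict positivity of area, finiteness, confidence range, and
#' (optionally) containment in a `width` x `height` frame.
#'
#' @param boxes box data.frame.
#' @param width,height optional frame bounds for containment checking.
#' @param stop. throw on failure (default) or return the message.
#' @return `TRUE` invisibly, or the failure message when `stop. = FALSE`.
#' @export
validateBoxes <- function(boxes, width = NULL, height = NULL, stop. = TRUE) {
  fail <- function(msg) if (stop.) stop(msg, call. = FALSE) else msg
  need <- c("xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(boxes)))
    return(fail("boxes need columns xmin, ymin, xmax, ymax"))
  if (nrow(boxes) == 0L) return(invisible(TRUE))
  co <- as.matrix(boxes[need])
  if (!all(is.finite(co))) return(fail("box coordinates must be finite"))
  if (any(boxes$xmin >= boxes$xmax) || any(boxes$ymin >= boxes$ymax))
    return(fail("degenerate box: xmin < xmax and ymin < ymax required"))
  if (!is.null(width) && (any(boxes$xmin < 0) || any(boxes$xmax > width)))
    return(fail("box outside [0, width)"))
  if (!is.null(height) && (any(boxes$ymin < 0) || any(boxes$ymax > height)))
    return(fail("box outside [0, height)"))
  if (!is.null(boxes$confidence) &&
      (any(boxes$confidence < 0) || any(boxes$confidence > 1)))
    return(fail("confidence must lie in [0, 1]"))
  invisible(TRUE)
}

#' Box areas in pixels
#'
#' @param boxes box data.frame.
#' @return numeric vector of `(xmax - xmin) * (ymax - ymin)`.
#' @export
boxArea <- function(boxes) {
  (boxes$xmax - boxes$xmin) * (boxes$ymax - boxes$ymin)
}

#' Intersection over union of two boxes
#'
#' Vectorized over paired rows: `a` and `b` must have the same number of
#' rows (or either may have one row, which is recycled). Disjoint pairs
#' give 0; degenerate (zero-area) boxes are an error.
#'
#' @param a,b box data.frames.
#' @return numeric vector of IoU values in \[0, 1\].
#' @examples
#' boxIoU(wslBoxes(0, 0, 10, 10), wslBoxes(5, 0, 15, 10))  # 1/3
#' @export
boxIoU <- function(a, b) {
  validateBoxes(a); validateBoxes(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != nrow(b) && nrow(a) != 1L && nrow(b) != 1L)
    stop("boxIoU: row counts must match or be 1")
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  iw <- pmin(a$xmax[ai], b$xmax[bi]) - pmax(a$xmin[ai], b$xmin[bi])
  ih <- pmin(a$ymax[ai], b$ymax[bi]) - pmax(a$ymin[ai], b$ymin[bi])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  inter / (boxArea(a)[ai] + boxArea(b)[bi] - inter)
}

#' All-pairs IoU matrix
#'
#' @param a,b box data.frames.
#' @return `nrow(a)` x `nrow(b)` matrix of IoU values.
#' @export
iouMatrix <- function(a, b) {
  validateBoxes(a); validateBoxes(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(0, nrow(a), nrow(b)))
  iw <- outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax)
  ih <- outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  inter / (outer(boxArea(a), boxArea(b), `+`) - inter)
}

#' Greedy non-maximum suppression
#'
#' Detections of one class, ranked by descending confidence (ties broken by
#' smaller row index, so the result is deterministic), are scanned once: a
#' detection is suppressed iff its IoU with an already-kept detection is
#' strictly greater than `iouThreshold`. The survivors are a subset of the
#' input in confidence order; the single highest-confidence detection is
#' always kept.
#'
#' @param dets detection data.frame (one class; callers partition by class).
#' @param iouThreshold suppression threshold in (0, 1).
#' @return the surviving rows of `dets`, ordered by descending confidence.
#' @examples
#' d <- wslBoxes(c(0, 2), c(0, 0), c(10, 12), c(10, 10),
#'               label = "wsl", confidence = c(0.9, 0.7))
#' nms(d, 0.5)  # only the 0.9 box survives
#' @export
nms <- function(dets, iouThreshold = 0.5) {
  stopifnot(iouThreshold > 0, iouThreshold < 1)
  if (is.null(dets) || nrow(dets) == 0L) return(dets)
  validateBoxes(dets)
  if (is.null(dets$confidence)) stop("nms needs a confidence column")
  ord <- order(-dets$confidence)  # stable: ties keep input order
  d <- dets[ord, , drop = FALSE]
  n <- nrow(d)
  keep <- logical(n)
  for (i in seq_len(n)) {
    kept <- which(keep)
    if (length(kept) == 0L) { keep[i] <- TRUE; next }
    ious <- boxIoU(d[rep(i, length(kept)), , drop = FALSE],
                   d[kept, , drop = FALSE])
    keep[i] <- all(ious <= iouThreshold)
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Round half away from zero toward the nearest integer
#'
#' Deterministic half-up rounding used at every frame boundary (base
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
roundHalfUp <- function(x) floor(x + 0.5)

#' Construct an ImageRecord
#'
#' @param imageId identifier.
#' @param width,height image dimensions in pixels.
#' @param annotations box data.frame with a `label` column; all boxes must
#'   lie within the image frame. Defaults to no annotations.
#' @return an [ImageRecord-class] object.
#' @export
ImageRecord <- function(imageId, width, height,
                        annotations = wslBoxes(numeric(), numeric(),
                                               numeric(), numeric(),
                                               label = character())) {
  if (is.null(annotations$label)) annotations$label <- character(nrow(annotations))
  new("ImageRecord", imageId = as.character(imageId),
      width = as.integer(width), height = as.integer(height),
      annotations = annotations)
}

#' @rdname imageId
#' @export
setMethod("imageId", "ImageRecord", function(object) object@imageId)

#' @rdname annotations
#' @export
setMethod("annotations", "ImageRecord", function(object) object@annotations)

#' @rdname imageDims
#' @export
setMethod("imageDims", "ImageRecord",
          function(object) c(width = object@width, height = object@height))

setMethod("show", "ImageRecord", function(object) {
  tab <- table(object@annotations$label)
  cat("ImageRecord '", object@imageId, "' ", object@width, "x",
      object@height, " px; ", nrow(object@annotations), " annotation(s)",
      if (length(tab)) paste0(" (", paste(names(tab), tab, sep = ": ",
                                          collapse = ", "), ")"),
      "\n", sep = "")
})
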