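#' @import methods
#' @importFrom stats quantile rnorm rpois runif rlnorm pchisq sd median setNames
#' @importFrom utils head read.csv write.csv
NULL

#' Isotropic resize transform between two pixel frames
#'
#' Records the single scale factor and the integer source/target canvas sizes
#' of a proportional ("fit within a square") resize. No padding or
#' letterboxing is involved: the target canvas is the scaled rectangle itself.
#'
#' @slot scale single positive scale factor (target = source * scale).
#' @slot sourceSize integer (width, height) of the source frame in pixels.
#' @slot targetSize integer (width, height) of the target frame in pixels.
#' @seealso [proportionalResize()], [rescaleBox()]
#' @export
setClass("ResizeTransform",
  representation(scale = "numeric", sourceSize = "integer",
                 targetSize = "integer"),
  validity = function(object) {
    if (length(object@scale) != 1L || !is.finite(object@scale) ||
        object@scale <= 0)
      return("scale must be a single positive finite number")
    if (length(object@sourceSize) != 2L || any(object@sourceSize < 1L))
      return("sourceSize must be two positive integers (width, height)")
    if (length(object@targetSize) != 2L || any(object@targetSize < 1L))
      return("targetSize must be two positive integers (width, height)")
    TRUE
  })

#' Overlapping sliding-window tile grid over a crop
#'
#' The ordered tile origins covering a crop with fixed-size windows and a
#' prescribed overlap between adjacent windows. Offsets advance by
#' `stride = window - overlap`; if the last regular tile does not reach the
#' crop edge a final tile clamped at `dim - window` is appended, so every
#' crop pixel is covered and all tiles lie inside the crop at native
#' resolution. When the crop is smaller than the window along an axis the
#' single tile spans the full extent of that axis.
#'
#' @slot window nominal window side in pixels.
#' @slot overlap minimum overlap between adjacent windows in pixels.
#' @slot stride window minus overlap.
#' @slot offsets integer matrix with columns `x`, `y`: tile origins in the
#'   crop frame, row-major order (x fastest).
#' @slot tileSize integer (width, height) actually used (window clamped to
#'   the crop extent).
#' @slot cropSize integer (width, height) of the tiled crop.
#' @seealso [tileGrid()]
#' @export
setClass("TileGrid",
  representation(window = "integer", overlap = "integer", stride = "integer",
                 offsets = "matrix", tileSize = "integer",
                 cropSize = "integer"),
  validity = function(object) {
    if (object@overlap < 0L || object@window <= object@overlap)
      return("window must exceed overlap and overlap must be >= 0")
    if (nrow(object@offsets) < 1L) return("at least one tile is required")
    TRUE
  })

#' One annotated image of the dataset
#'
#' Image identity, pixel dimensions, and the ground-truth annotations
#' (axis-aligned boxes with a class label) expressed in the original image
#' frame with the package-wide 0-based half-open pixel convention.
#'
#' @slot imageId character scalar identifier.
#' @slot width,height image dimensions in pixels.
#' @slot annotations data.frame with columns `xmin`, `ymin`, `xmax`, `ymax`,
#'   `label`; every box lies within `[0, width) x [0, height)`.
#' @seealso [ImageRecord()], [annotations()]
#' @export
setClass("ImageRecord",
  representation(imageId = "character", width = "integer", height = "integer",
                 annotations = "data.frame"),
  validity = function(object) {
    if (length(object@imageId) != 1L) return("imageId must be a scalar")
    if (object@width < 1L || object@height < 1L)
      return("width and height must be positive")
    ann <- object@annotations
    need <- c("xmin", "ymin", "xmax", "ymax", "label")
    if (!all(need %in% names(ann)))
      return("annotations need columns xmin, ymin, xmax, ymax, label")
    if (nrow(ann)) {
      bad <- validateBoxes(ann, width = object@width, height = object@height,
                           stop. = FALSE)
      if (!isTRUE(bad)) return(bad)
    }
    TRUE
  })

#' Classical blob-based reference detector
#'
#' A deterministic brightness-thresholding detector fulfilling the detector
#' contract, so the tiled pipeline runs end-to-end without trained network
#' weights. Pixels are reduced to a weighted-channel saliency map,
#' binarized, cleaned by morphological opening, and grouped into
#' 8-connected components; components within the area limits become
#' detections whose confidence is the mean saliency of their pixels (capped
#' at 1). The confidence rule is plumbing, not a calibrated probability.
#'
#' @slot label class label attached to every detection.
#' @slot channelWeights length-3 non-negative weights reducing RGB to
#'   saliency (grayscale input uses the map as-is).
#' @slot threshold binarization threshold in (0, 1).
#' @slot minArea,maxArea component pixel-count limits (min < max).
#' @slot openRadius morphological opening radius in pixels (0 disables).
#' @seealso [blobDetector()], [detect()]
#' @export
setClass("BlobDetector",
  representation(label = "character", channelWeights = "numeric",
                 threshold = "numeric", minArea = "numeric",
                 maxArea = "numeric", openRadius = "numeric"),
  validity = function(object) {
    if (object@threshold <= 0 || object@threshold >= 1)
      return("threshold must lie in (0, 1)")
    if (object@minArea >= object@maxArea)
      return("minArea must be smaller than maxArea")
    if (length(object@channelWeights) != 3L || any(object@channelWeights < 0))
      return("channelWeights must be 3 non-negative numbers")
    if (object@openRadius < 0) return("openRadius must be >= 0")
    TRUE
  })

#' Fixture backend exposing hand-specified activation maps
#'
#' A detector-contract backend whose `activations()` are deterministic
#' indicator maps (equal vertical bands of the image, one per channel; two
#' channels give the left/right half-planes). Used to exercise score-CAM
#' against closed-form expectations.
#'
#' @slot nChannels number of activation channels (>= 1).
#' @seealso [toyActivationsBackend()], [activations()], [scoreCam()]
#' @export
setClass("ToyActivationsBackend",
  representation(nChannels = "integer"),
  validity = function(object) {
    if (object@nChannels < 1L) return("nChannels must be >= 1")
    TRUE
  })

#' Dataset-level accuracy report
#'
#' The evaluation-suite output for one detector arm: pixel-wise Cohen's
#' kappa, 101-point AP at IoU 0.5, mAP over IoU 0.50--0.95, the F1-over-IoU
#' curve, TP/FN/FP counts with the operating confidence cutoff, precision
#' and recall, and percentile-bootstrap 95% confidence intervals.
#'
#' @slot kappa pooled pixel-wise Cohen's kappa.
#' @slot ap50 average precision at IoU 0.5 (101-point interpolation).
#' @slot map mean AP over IoU thresholds 0.50 to 0.95 step 0.05.
#' @slot f1Curve data.frame with columns `iou`, `f1`.
#' @slot tp,fn,fp counts at IoU 0.5 and the operating cutoff.
#' @slot precision,recall rates at the same operating point.
#' @slot cutoff confidence cutoff used for counts/F1 (maximizes F1 at 0.5).
#' @slot ci named list of `c(lo, hi)` bootstrap intervals (may be empty).
#' @seealso [evaluateDetections()]
#' @export
setClass("EvaluationReport",
  representation(kappa = "numeric", ap50 = "numeric", map = "numeric",
                 f1Curve = "data.frame", tp = "integer", fn = "integer",
                 fp = "integer", precision = "numeric", recall = "numeric",
                 cutoff = "numeric", ci = "list"))

#' Box-area summary with COCO size classes
#'
#' Median and interquartile range of box areas (linear-interpolation,
#' type-7 quantiles) and the counts per COCO size class: small (< 1024 px),
#' medium (1024 to < 9216 px), large (>= 9216 px).
#'
#' @slot median,q1,q3 area quantiles in pixels.
#' @slot counts named integer vector (small, medium, large).
#' @slot n number of boxes summarized.
#' @seealso [areaStats()], [cocoSizeClass()]
#' @export
setClass("SizeStats",
  representation(median = "numeric", q1 = "numeric", q3 = "numeric",
                 counts = "integer", n = "integer"),
  validity = function(object) {
    if (object@n > 0 && !(object@q1 <= object@median &&
                          object@median <= object@q3))
      return("quantiles must satisfy q1 <= median <= q3")
    if (sum(object@counts) != object@n)
      return("size-class counts must sum to the box count")
    TRUE
  })

#' Accumulated spatial heatmap
#'
#' A non-negative accumulation grid over either the normalized image frame
#' (absolute variant) or the tooth-relative unit square (relative variant).
#' Each box deposits its exact fractional coverage of every grid cell,
#' scaled so one full-frame box contributes 1 to every cell.
#'
#' @slot grid numeric matrix (gridSize x gridSize), x along rows.
#' @slot frame `"image"` or `"tooth"`.
#' @slot dropped number of lesions not assignable to any tooth (relative
#'   variant only).
#' @seealso [absoluteHeatmap()], [relativeHeatmap()]
#' @export
setClass("SpatialHeatmap",
  representation(grid = "matrix", frame = "character", dropped = "integer"),
  validity = function(object) {
    if (any(object@grid < 0)) return("heatmap values must be >= 0")
    if (!object@frame %in% c("image", "tooth"))
      return("frame must be 'image' or 'tooth'")
    TRUE
  })
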