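#' Run a detector backend on an image
#'
#' The detector contract: given an image (EBImage `Image` or numeric array
#' with x as the first dimension, values in \[0, 1\]), return a detection
#' data.frame with columns `xmin`, `ymin`, `xmax`, `ymax`, `label`,
#' `confidence`, sorted by descending confidence, all boxes inside the
#' presented image's bounds. Must be deterministic for a fixed image and
#' configuration.
#'
#' @param object a detector backend.
#' @param image the image to analyze.
#' @param ... backend-specific arguments.
#' @return detection data.frame (possibly zero rows).
#' @export
setGeneric("detect", function(object, image, ...) standardGeneric("detect"))

#' Activation channel maps of a detector backend
#'
#' Optional capability of the detector contract, required by score-CAM:
#' a list of numeric matrices (one per channel) with values in \[0, 1\].
#' Backends without activations signal a capability error.
#'
#' @param object a detector backend.
#' @param image the image to analyze.
#' @param ... backend-specific arguments.
#' @return list of numeric matrices.
#' @export
setGeneric("activations",
           function(object, image, ...) standardGeneric("activations"))

#' @describeIn ImageRecord-class image identifier accessor.
#' @param object an `ImageRecord`.
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))

#' @describeIn ImageRecord-class annotation data.frame accessor.
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))

#' @describeIn ImageRecord-class image dimensions accessor, `c(width, height)`.
#' @export
setGeneric("imageDims", function(object) standardGeneric("imageDims"))

#' @describeIn TileGrid-class tile origin matrix accessor.
#' @param object a `TileGrid`.
#' @export
setGeneric("tileOffsets", function(object) standardGeneric("tileOffsets"))
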