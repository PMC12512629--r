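# Detector backends. The pipeline takes any object with a detect() method
# honoring the contract in ?detect; score-CAM additionally needs
# activations(). The bundled blob detector is classical plumbing that makes
# the artifact runnable end-to-end without trained network weights -- its
# confidence rule (mean component saliency, capped at 1) is documented as
# non-physical.

#' Construct the blob reference detector
#'
#' @param label class label for the detections (e.g. `"tooth"` or `"wsl"`).
#' @param threshold saliency binarization threshold in (0, 1).
#' @param minArea,maxArea component pixel-count limits.
#' @param openRadius morphological opening radius in px (0 disables).
#' @param channelWeights RGB-to-saliency weights (default ITU-R BT.601 luma).
#' @return a [BlobDetector-class].
#' @examples
#' det <- blobDetector("wsl", threshold = 0.85, minArea = 64)
#' @export
blobDetector <- function(label, threshold = 0.5, minArea = 100,
                         maxArea = 1e6, openRadius = 0,
                         channelWeights = c(0.299, 0.587, 0.114)) {
  new("BlobDetector", label = as.character(label),
      threshold = as.numeric(threshold), minArea = as.numeric(minArea),
      maxArea = as.numeric(maxArea), openRadius = as.numeric(openRadius),
      channelWeights = as.numeric(channelWeights))
}

# EBImage::bwlabel is 4-connected; merge labels that touch diagonally to
# obtain the 8-connected components the blob contract requires.
.label8 <- function(binary) {
  lab <- EBImage::imageData(EBImage::bwlabel(binary))
  n <- as.integer(max(lab))
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  W <- nrow(lab); H <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-W, -H]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -H]), as.vector(lab[-W, -1])))  # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) unite(pairs[r, 1], pairs[r, 2])
    roots <- vapply(seq_len(n), find, integer(1))
    lab[lab > 0] <- roots[lab[lab > 0]]
  }
  lab
}

#' @describeIn blobDetector detect blobs: saliency -> threshold ->
#'   morphological opening -> 8-connected components -> area filter ->
#'   bounding boxes, confidence = capped mean component saliency.
#'   Deterministic; output sorted by descending confidence.
#' @param object a [BlobDetector-class].
#' @param image image or numeric array (x first), values in \[0, 1\].
#' @param ... ignored.
#' @export
setMethod("detect", "BlobDetector", function(object, image, ...) {
  sal <- .saliencyMap(image, object@channelWeights)
  if (length(sal) == 0L) stop("empty image")
  binary <- sal > object@threshold
  if (object@openRadius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(object@openRadius) + 1L,
                                shape = "disc")
    binary <- EBImage::imageData(EBImage::opening(binary, brush)) > 0
  }
  empty <- wslBoxes(numeric(), numeric(), numeric(), numeric(),
                    label = character(), confidence = numeric())
  if (!any(binary)) return(empty)
  lab <- .label8(binary)
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  sizes <- tabulate(comp)
  keepIds <- which(sizes >= object@minArea & sizes <= object@maxArea)
  if (length(keepIds) == 0L) return(empty)
  rows <- split(seq_len(nrow(idx)), comp)[as.character(keepIds)]
  out <- do.call(rbind, lapply(rows, function(r) {
    x <- idx[r, 1]; y <- idx[r, 2]
    data.frame(xmin = min(x) - 1, ymin = min(y) - 1,
               xmax = max(x), ymax = max(y),
               confidence = min(1, mean(sal[idx[r, , drop = FALSE]])))
  }))
  out$label <- object@label
  out <- out[order(-out$confidence), c("xmin", "ymin", "xmax", "ymax",
                                       "label", "confidence")]
  rownames(out) <- NULL
  out
})

setMethod("activations", "BlobDetector", function(object, image, ...) {
  stop("BlobDetector exposes no activation maps (capability error); ",
       "use a backend with activations() for score-CAM", call. = FALSE)
})

setMethod("show", "BlobDetector", function(object) {
  cat(sprintf(
    "BlobDetector('%s'): threshold %.3g, area [%g, %g] px, opening r=%g\n",
    object@label, object@threshold, object@minArea, object@maxArea,
    object@openRadius))
})

#' Construct the toy activations backend
#'
#' @param nChannels number of activation channels; channel `k` of `n` is
#'   the indicator of the k-th of `n` equal vertical bands (for `n = 2`:
#'   left and right half-planes).
#' @return a [ToyActivationsBackend-class].
#' @export
toyActivationsBackend <- function(nChannels = 2L) {
  new("ToyActivationsBackend", nChannels = as.integer(nChannels))
}

#' @describeIn toyActivationsBackend deterministic vertical-band indicator
#'   maps at the image's spatial dimensions.
#' @param object a [ToyActivationsBackend-class].
#' @param image image or numeric array (x first).
#' @param ... ignored.
#' @export
setMethod("activations", "ToyActivationsBackend", function(object, image, ...) {
  sz <- .imageSize(image)
  n <- object@nChannels
  edges <- round(seq(0, sz[1], length.out = n + 1))
  lapply(seq_len(n), function(k) {
    m <- matrix(0, sz[1], sz[2])
    if (edges[k + 1] > edges[k]) m[(edges[k] + 1):edges[k + 1], ] <- 1
    m
  })
})

# --- backend registry -------------------------------------------------------

.detectorRegistry <- new.env(parent = emptyenv())

#' Register a detector backend constructor
#'
#' Backends are keyed by name so configuration files can request
#' `"<name>:<key>=<value>,..."` specs. The bundled `"blob"` backend is
#' pre-registered.
#'
#' @param name backend name.
#' @param constructor function taking the parsed key-value parameters.
#' @return invisibly, the constructor.
#' @export
registerDetector <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = .detectorRegistry)
  invisible(constructor)
}

#' Build a detector from a config spec string
#'
#' Parses `"name:key=value,key=value"` (values coerced to numeric where
#' possible) and calls the registered constructor.
#'
#' @param spec spec string, e.g. `"blob:label=wsl,threshold=0.85,minArea=64"`.
#' @return a detector backend.
#' @export
detectorFromSpec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  name <- parts[1]
  if (!exists(name, envir = .detectorRegistry))
    stop("unknown detector backend '", name, "'")
  args <- list()
  if (length(parts) > 1 && nzchar(parts[2])) {
    kv <- strsplit(strsplit(parts[2], ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
    args <- lapply(kv, function(p) {
      v <- suppressWarnings(as.numeric(p[2]))
      if (is.na(v)) p[2] else v
    })
    names(args) <- vapply(kv, `[`, "", 1)
  }
  do.call(get(name, envir = .detectorRegistry), args)
}

registerDetector("blob", blobDetector)
registerDetector("toy", toyActivationsBackend)

#' Reference detector pair for the synthetic material
#'
#' The canonical blob configurations used throughout examples and the
#' reproduction script: the tooth detector thresholds at the
#' tooth/background brightness midpoint and expects tooth-sized
#' components on a fit-sized image; the lesion detector thresholds
#' between tooth and lesion brightness with a minimum component area of
#' 64 px, which is what makes it sharp at native resolution and
#' progressively blind to lesions shrunk into the small-object regime by
#' downscaling.
#'
#' @return named list with elements `tooth` and `wsl`
#'   ([BlobDetector-class] objects).
#' @export
referenceDetectors <- function() {
  list(tooth = blobDetector("tooth", threshold = 0.5, minArea = 300),
       wsl = blobDetector("wsl", threshold = 0.88, minArea = 64))
}
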