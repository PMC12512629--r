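#' Plot a precision-recall curve
#'
#' @param pr a [prCurve()] data.frame.
#' @param path optional PNG path; `NULL` draws on the active device.
#' @param main plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plotPrCurve <- function(pr, path = NULL, main = "Precision-recall (IoU 0.5)") {
  if (!is.null(path)) grDevices::png(path, width = 720, height = 600)
  graphics::plot(c(0, pr$recall), c(1, pr$precision), type = "s",
                 xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                 ylab = "Precision", main = main, lwd = 2, col = "steelblue")
  if (!is.null(path)) grDevices::dev.off()
  invisible(path)
}

#' Plot an F1-over-IoU-threshold curve
#'
#' @param f1c an [f1OverIou()] data.frame.
#' @param path optional PNG path.
#' @param main plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plotF1Curve <- function(f1c, path = NULL, main = "F1 over IoU threshold") {
  if (!is.null(path)) grDevices::png(path, width = 720, height = 600)
  graphics::plot(f1c$iou, f1c$f1, type = "b", ylim = c(0, 1),
                 xlab = "IoU threshold", ylab = "F1", main = main,
                 lwd = 2, col = "firebrick", pch = 16)
  if (!is.null(path)) grDevices::dev.off()
  invisible(path)
}

#' Render a heatmap grid to PNG (max-normalized)
#'
#' @param heatmap a [SpatialHeatmap-class].
#' @param path optional PNG path.
#' @param main plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
renderHeatmap <- function(heatmap, path = NULL, main = NULL) {
  g <- heatmap@grid
  if (max(g) > 0) g <- g / max(g)  # normalized max = 1 for rendering
  if (is.null(main))
    main <- if (heatmap@frame == "tooth") "Tooth-relative lesion locations"
            else "Lesion locations (image frame)"
  if (!is.null(path)) grDevices::png(path, width = 640, height = 640)
  graphics::image(seq_len(nrow(g)), seq_len(ncol(g)),
                  g[, rev(seq_len(ncol(g)))],
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "x", ylab = "y", main = main, useRaster = TRUE)
  if (!is.null(path)) grDevices::dev.off()
  invisible(path)
}
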