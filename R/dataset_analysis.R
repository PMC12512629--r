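# Dataset-geometry analyses: box-area statistics with COCO size classes,
# the shift of those classes under downscaling, a Pearson 2x2 chi-square,
# absolute and tooth-relative location heatmaps, and crown-coverage
# fractions. All of it works on bounding-box geometry only -- the only
# geometry box annotations provide.

#' COCO size class of box areas
#'
#' @param areas numeric vector of box areas in pixels.
#' @return factor with levels `small` (< 1024 px = 32^2),
#'   `medium` (1024 to < 9216 px = 96^2), `large` (>= 9216 px).
#' @export
cocoSizeClass <- function(areas) {
  cut(areas, breaks = c(-Inf, 1024, 9216, Inf),
      labels = c("small", "medium", "large"), right = FALSE)
}

#' Box-area summary statistics
#'
#' Median and IQR of box areas using linear-interpolation (type-7)
#' quantiles, plus counts per COCO size class.
#'
#' @param boxes box data.frame.
#' @return a [SizeStats-class].
#' @export
areaStats <- function(boxes) {
  a <- boxArea(boxes)
  n <- length(a)
  q <- if (n) quantile(a, c(0.25, 0.5, 0.75), names = FALSE, type = 7) else
    rep(NA_real_, 3)
  counts <- if (n) table(cocoSizeClass(a)) else
    table(cocoSizeClass(numeric()))
  new("SizeStats", median = q[2], q1 = q[1], q3 = q[3],
      counts = setNames(as.integer(counts), names(counts)),
      n = as.integer(n))
}

setMethod("show", "SizeStats", function(object) {
  cat(sprintf(
    "SizeStats: n = %d, median area %.1f px (IQR %.1f-%.1f); %s\n",
    object@n, object@median, object@q1, object@q3,
    paste(names(object@counts), object@counts, sep = ": ", collapse = ", ")))
})

#' Area-class shift under downscaling
#'
#' Applies the squared scale of a resize transform to every box area and
#' recomputes the size statistics, quantifying how proportional resizing
#' pushes boxes into the small-object class.
#'
#' @param boxes box data.frame at source resolution.
#' @param transform a [ResizeTransform-class].
#' @return list with elements `before` and `after` ([SizeStats-class]).
#' @export
downscaleShift <- function(boxes, transform) {
  before <- areaStats(boxes)
  scaled <- boxes
  s <- transform@scale  # isotropic: areas scale by scale^2
  for (col in c("xmin", "ymin", "xmax", "ymax"))
    scaled[[col]] <- boxes[[col]] * s
  list(before = before, after = areaStats(scaled))
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' `sum((O - E)^2 / E)` with marginal-product expected counts, no
#' continuity correction, 1 degree of freedom. All expected counts must be
#' strictly positive.
#'
#' @param table 2x2 matrix of counts.
#' @return list with `statistic`, `p.value`, `expected`, `df`.
#' @export
chiSquare2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) stop("all expected counts must be > 0")
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE),
       expected = expected, df = 1L)
}

# Deposit each box's exact fractional coverage of every grid cell of the
# unit square; a cell fully inside a box accumulates 1.
.accumulateUnitBoxes <- function(grid, gridSize, xmin, ymin, xmax, ymax) {
  edges <- seq(0, 1, length.out = gridSize + 1)
  for (i in seq_along(xmin)) {
    xo <- pmax(0, pmin(edges[-1], xmax[i]) - pmax(edges[-(gridSize + 1)], xmin[i]))
    yo <- pmax(0, pmin(edges[-1], ymax[i]) - pmax(edges[-(gridSize + 1)], ymin[i]))
    grid <- grid + outer(xo, yo) * gridSize^2
  }
  grid
}

#' Absolute location heatmap
#'
#' Each box, normalized by its own image's dimensions, is rasterized into
#' a grid over the unit square and accumulated over the dataset. Total
#' accumulated mass equals the sum of normalized box areas times the cell
#' count.
#'
#' @param boxes box data.frame.
#' @param widths,heights per-box image dimensions (recycled if scalar).
#' @param gridSize grid resolution (default 64).
#' @return a [SpatialHeatmap-class] in the `"image"` frame.
#' @export
absoluteHeatmap <- function(boxes, widths, heights, gridSize = 64L) {
  n <- nrow(boxes)
  widths <- rep_len(widths, n); heights <- rep_len(heights, n)
  grid <- matrix(0, gridSize, gridSize)
  if (n)
    grid <- .accumulateUnitBoxes(grid, gridSize,
                                 boxes$xmin / widths, boxes$ymin / heights,
                                 boxes$xmax / widths, boxes$ymax / heights)
  new("SpatialHeatmap", grid = grid, frame = "image", dropped = 0L)
}

#' Tooth-relative location heatmap
#'
#' Assigns each lesion to the tooth box of maximal intersection area
#' (lesions intersecting no tooth are dropped and counted), expresses the
#' lesion box in the host tooth's unit square, and accumulates the
#' rasterized boxes. The gingival-band concentration of lesions shows up
#' as peripheral mass in this frame.
#'
#' @param lesionList list of per-image lesion box data.frames.
#' @param toothList list of per-image tooth box data.frames (same order).
#' @param gridSize grid resolution (default 64).
#' @return a [SpatialHeatmap-class] in the `"tooth"` frame; slot `dropped`
#'   counts unassignable lesions.
#' @export
relativeHeatmap <- function(lesionList, toothList, gridSize = 64L) {
  stopifnot(length(lesionList) == length(toothList))
  grid <- matrix(0, gridSize, gridSize)
  dropped <- 0L
  for (i in seq_along(lesionList)) {
    les <- lesionList[[i]]; teeth <- toothList[[i]]
    if (is.null(les) || nrow(les) == 0L) next
    if (is.null(teeth) || nrow(teeth) == 0L) { dropped <- dropped + nrow(les); next }
    iw <- outer(les$xmax, teeth$xmax, pmin) - outer(les$xmin, teeth$xmin, pmax)
    ih <- outer(les$ymax, teeth$ymax, pmin) - outer(les$ymin, teeth$ymin, pmax)
    inter <- pmax(iw, 0) * pmax(ih, 0)
    host <- apply(inter, 1, which.max)
    assigned <- apply(inter, 1, max) > 0
    dropped <- dropped + sum(!assigned)
    if (!any(assigned)) next
    l <- les[assigned, , drop = FALSE]
    t <- teeth[host[assigned], , drop = FALSE]
    tw <- t$xmax - t$xmin; th <- t$ymax - t$ymin
    grid <- .accumulateUnitBoxes(grid, gridSize,
      pmax(0, (l$xmin - t$xmin) / tw), pmax(0, (l$ymin - t$ymin) / th),
      pmin(1, (l$xmax - t$xmin) / tw), pmin(1, (l$ymax - t$ymin) / th))
  }
  new("SpatialHeatmap", grid = grid, frame = "tooth",
      dropped = as.integer(dropped))
}

setMethod("show", "SpatialHeatmap", function(object) {
  cat(sprintf(
    "SpatialHeatmap (%s frame): %dx%d grid, total mass %.2f%s\n",
    object@frame, nrow(object@grid), ncol(object@grid), sum(object@grid),
    if (object@dropped > 0) sprintf(", %d lesion(s) dropped", object@dropped)
    else ""))
})

#' Mass fraction in the peripheral band of a unit-square heatmap
#'
#' The peripheral band is the outer margin of the unit square (default
#' depth 0.25 on every side); the complement is the central region.
#'
#' @param heatmap a [SpatialHeatmap-class].
#' @param band margin depth in unit-square coordinates.
#' @return fraction of total mass lying in the band (NA for empty grids).
#' @export
peripheralMassFraction <- function(heatmap, band = 0.25) {
  g <- heatmap@grid
  n <- nrow(g)
  centers <- (seq_len(n) - 0.5) / n
  central <- centers >= band & centers <= 1 - band
  total <- sum(g)
  if (total == 0) return(NA_real_)
  1 - sum(g[central, central]) / total
}

#' Fraction of a tooth crown covered by lesions
#'
#' Exact area of the union of the lesion boxes clipped to the tooth box,
#' divided by the tooth-box area (overlapping lesions are counted once).
#' Computed by a coordinate-compression sweep, not rasterization.
#'
#' @param lesionBoxes lesion box data.frame.
#' @param toothBox one-row tooth box data.frame.
#' @return coverage fraction in \[0, 1\].
#' @export
crownCoverage <- function(lesionBoxes, toothBox) {
  validateBoxes(toothBox)
  if (is.null(lesionBoxes) || nrow(lesionBoxes) == 0L) return(0)
  l <- lesionBoxes
  l$xmin <- pmax(l$xmin, toothBox$xmin); l$xmax <- pmin(l$xmax, toothBox$xmax)
  l$ymin <- pmax(l$ymin, toothBox$ymin); l$ymax <- pmin(l$ymax, toothBox$ymax)
  l <- l[l$xmin < l$xmax & l$ymin < l$ymax, , drop = FALSE]
  if (nrow(l) == 0L) return(0)
  rectUnionArea(l) / boxArea(toothBox)
}

#' Exact area of a union of axis-aligned rectangles
#'
#' Coordinate-compression sweep along x: within each x-slab the union
#' length of the active y-intervals is computed by interval merging.
#'
#' @param boxes box data.frame.
#' @return the union area.
#' @export
rectUnionArea <- function(boxes) {
  if (nrow(boxes) == 0L) return(0)
  xs <- sort(unique(c(boxes$xmin, boxes$xmax)))
  area <- 0
  for (i in seq_len(length(xs) - 1L)) {
    x0 <- xs[i]; x1 <- xs[i + 1]
    act <- boxes$xmin <= x0 & boxes$xmax >= x1
    if (!any(act)) next
    ys <- cbind(boxes$ymin[act], boxes$ymax[act])
    ys <- ys[order(ys[, 1]), , drop = FALSE]
    len <- 0; curLo <- ys[1, 1]; curHi <- ys[1, 2]
    for (j in seq_len(nrow(ys))[-1]) {
      if (ys[j, 1] > curHi) { len <- len + curHi - curLo
        curLo <- ys[j, 1]; curHi <- ys[j, 2]
      } else curHi <- max(curHi, ys[j, 2])
    }
    len <- len + curHi - curLo
    area <- area + (x1 - x0) * len
  }
  area
}
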