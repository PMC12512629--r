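# Seeded generator of intra-oral-photograph-like images with ground-truth
# labels: two arches of bright rounded tooth rectangles on a dark oral
# background, with bright elliptical lesion blobs planted inside tooth
# boxes, concentrated in the peri-gingival periphery. Lesion box areas are
# log-normal with a median of 2898 px at 4000x3000 (scaled with image
# area otherwise). Brightness contrasts are chosen so the blob reference
# detector is near-perfect at native resolution and degrades after
# proportional downscaling -- a fixture property that makes the
# tiled-vs-baseline comparison meaningful by construction, not a
# biological claim.

#' Generator configuration
#'
#' @param imageWidth,imageHeight canvas in pixels (default 4000 x 3000;
#'   a 1600 x 1200 preset keeps test runs light).
#' @param teethPerArch teeth per arch row (two arches).
#' @param lesionRate Poisson mean lesion count per image (default 13,
#'   matching roughly 13 lesions per photograph in the emulated material).
#' @param medianLesionArea median lesion box area in px; default 2898
#'   scaled by the canvas area relative to 4000 x 3000.
#' @param sdlogArea log-sd of the log-normal area distribution (default
#'   0.731, fitted so the quartiles fall near 1895 and 5080 px at full
#'   scale).
#' @param peripheralProb probability a lesion center lies in the outer
#'   25% band of its tooth's unit square (default 0.8).
#' @param gingivalWeight probability mass of the gingival side among
#'   peripheral placements (remainder split 0.2 incisal / 0.15 + 0.15
#'   mesial-distal).
#' @param upperJawBias probability a lesion sits on the upper arch.
#' @param toothFill,lesionFill,background RGB triples in \[0, 1\].
#' @param noiseSd Gaussian pixel noise sd added to all channels.
#' @param seed RNG seed; all randomness flows through it.
#' @return validated configuration list of class `"GeneratorConfig"`.
#' @export
generatorConfig <- function(imageWidth = 4000L, imageHeight = 3000L,
                            teethPerArch = 10L, lesionRate = 13,
                            medianLesionArea = NULL, sdlogArea = 0.731,
                            peripheralProb = 0.8, gingivalWeight = 0.5,
                            upperJawBias = 0.6,
                            toothFill = c(0.82, 0.80, 0.70),
                            lesionFill = c(0.97, 0.97, 0.93),
                            background = c(0.35, 0.16, 0.16),
                            noiseSd = 0.02, seed = 1L) {
  if (is.null(medianLesionArea))
    medianLesionArea <- 2898 * (imageWidth * imageHeight) / (4000 * 3000)
  stopifnot(imageWidth >= 400, imageHeight >= 300, teethPerArch >= 2,
            lesionRate >= 0, medianLesionArea > 0, sdlogArea > 0,
            peripheralProb >= 0, peripheralProb <= 1,
            gingivalWeight >= 0, gingivalWeight <= 1,
            upperJawBias >= 0, upperJawBias <= 1, noiseSd >= 0)
  structure(list(imageWidth = as.integer(imageWidth),
                 imageHeight = as.integer(imageHeight),
                 teethPerArch = as.integer(teethPerArch),
                 lesionRate = lesionRate,
                 medianLesionArea = medianLesionArea,
                 sdlogArea = sdlogArea, peripheralProb = peripheralProb,
                 gingivalWeight = gingivalWeight,
                 upperJawBias = upperJawBias, toothFill = toothFill,
                 lesionFill = lesionFill, background = background,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' @export
print.GeneratorConfig <- function(x, ...) {
  cat(sprintf(paste0("GeneratorConfig: %dx%d px, %d teeth/arch, ",
                     "lesion rate %.3g, median area %.0f px, ",
                     "peripheral prob %.2f, upper-jaw bias %.2f, seed %d\n"),
              x$imageWidth, x$imageHeight, x$teethPerArch, x$lesionRate,
              x$medianLesionArea, x$peripheralProb, x$upperJawBias, x$seed))
  invisible(x)
}

# Sample one image's layout from the current RNG stream. Teeth are laid
# out in two arch rows; each lesion is assigned a host tooth, a
# log-normal area, and a position in the tooth's unit square (peripheral
# band with the configured probability; gingival side = tooth top for
# the upper arch, tooth bottom for the lower).
.sampleLayout <- function(cfg) {
  W <- cfg$imageWidth; H <- cfg$imageHeight
  marginX <- 0.08 * W
  slot <- (W - 2 * marginX) / cfg$teethPerArch
  arch <- function(yAnchor, down) {
    k <- cfg$teethPerArch
    tw <- slot * 0.88 * runif(k, 0.92, 1)
    th <- 0.24 * H * runif(k, 0.85, 1)
    x0 <- marginX + (seq_len(k) - 1) * slot + slot * 0.06 +
      runif(k, -0.02, 0.02) * slot
    y0 <- if (down) yAnchor + runif(k, -0.01, 0.01) * H else
      yAnchor - th + runif(k, -0.01, 0.01) * H
    data.frame(xmin = roundHalfUp(pmax(0, x0)),
               ymin = roundHalfUp(pmax(0, y0)),
               xmax = roundHalfUp(pmin(W, x0 + tw)),
               ymax = roundHalfUp(pmin(H, if (down) y0 + th else y0 + th)))
  }
  upper <- arch(0.17 * H, down = TRUE)   # gingival side: tooth top
  lower <- arch(0.83 * H, down = FALSE)  # gingival side: tooth bottom
  teeth <- rbind(upper, lower)
  teeth$label <- "tooth"
  teeth$arch <- rep(c("upper", "lower"), each = cfg$teethPerArch)

  nLesions <- rpois(1, cfg$lesionRate)
  lesions <- NULL
  if (nLesions > 0) {
    placed <- NULL  # distinct lesions get disjoint boxes (retried placement)
    rows <- lapply(seq_len(nLesions), function(j) {
      for (try in 1:12) {
        cand <- .placeLesion(cfg, teeth)
        clear <- is.null(placed) ||
          all(pmin(placed$xmax, cand$xmax) <= pmax(placed$xmin, cand$xmin) |
              pmin(placed$ymax, cand$ymax) <= pmax(placed$ymin, cand$ymin))
        if (clear) break
      }
      placed <<- rbind(placed, cand)
      cand
    })
    lesions <- do.call(rbind, rows)
    lesions$label <- "wsl"
  }
  list(teeth = teeth, lesions = lesions, width = W, height = H)
}

# sample one lesion box (host tooth, log-normal area, position in the
# tooth's unit square) from the current RNG stream
.placeLesion <- function(cfg, teeth) {
  onUpper <- runif(1) < cfg$upperJawBias
  ti <- sample.int(cfg$teethPerArch, 1) +
    if (onUpper) 0L else cfg$teethPerArch
  t <- teeth[ti, ]
  tw <- t$xmax - t$xmin; th <- t$ymax - t$ymin
  area <- rlnorm(1, log(cfg$medianLesionArea), cfg$sdlogArea)
  aspect <- exp(rnorm(1, 0, 0.25))
  w <- min(sqrt(area * aspect), 0.45 * tw)
  h <- min(sqrt(area / aspect), 0.45 * th)
  w <- max(w, 4); h <- max(h, 4)
  hw <- (w / 2) / tw; hh <- (h / 2) / th  # half-extents, unit square
  gw <- cfg$gingivalWeight
  side <- if (runif(1) < cfg$peripheralProb) {
    sample(c("gingival", "incisal", "mesial", "distal"), 1,
           prob = c(gw, (1 - gw) * 0.4, (1 - gw) * 0.3, (1 - gw) * 0.3))
  } else "central"
  gingivalTop <- onUpper  # image-frame side holding the gum line
  inBand <- function(lo, hi) runif(1, lo, hi)
  u <- NA; v <- NA
  if (side == "central") {
    u <- inBand(max(0.25, hw), min(0.75, 1 - hw))
    v <- inBand(max(0.25, hh), min(0.75, 1 - hh))
  } else if (side %in% c("gingival", "incisal")) {
    atTop <- (side == "gingival") == gingivalTop
    v <- if (atTop) inBand(hh, 0.25) else inBand(0.75, 1 - hh)
    u <- inBand(hw, 1 - hw)
  } else {
    u <- if (side == "mesial") inBand(hw, 0.25) else inBand(0.75, 1 - hw)
    v <- inBand(hh, 1 - hh)
  }
  cx <- t$xmin + u * tw; cy <- t$ymin + v * th
  x0 <- roundHalfUp(cx - w / 2); y0 <- roundHalfUp(cy - h / 2)
  x1 <- min(x0 + max(4, roundHalfUp(w)), t$xmax)
  y1 <- min(y0 + max(4, roundHalfUp(h)), t$ymax)
  x0 <- max(x0, t$xmin); y0 <- max(y0, t$ymin)
  data.frame(xmin = x0, ymin = y0, xmax = x1, ymax = y1)
}

# Render a layout to a W x H x 3 array: background + teeth (rounded
# rectangles) + lesion ellipses, then Gaussian noise on all channels.
.renderLayout <- function(layout, cfg) {
  W <- layout$width; H <- layout$height
  img <- array(0, dim = c(W, H, 3))
  for (c in 1:3) img[, , c] <- cfg$background[c]
  teeth <- layout$teeth
  for (i in seq_len(nrow(teeth))) {
    xs <- (teeth$xmin[i] + 1):teeth$xmax[i]
    ys <- (teeth$ymin[i] + 1):teeth$ymax[i]
    r <- max(2, round(0.12 * min(length(xs), length(ys))))
    # rounded-corner mask: drop pixels outside the corner quarter-discs
    cornerDrop <- function(cxs, cys, ox, oy) {
      dx <- outer((cxs - ox)^2, rep(1, length(cys)))
      dy <- outer(rep(1, length(cxs)), (cys - oy)^2)
      (dx + dy) > r^2
    }
    mask <- matrix(TRUE, length(xs), length(ys))
    ix <- seq_len(r); iyTop <- seq_len(r); iyBot <- length(ys) - r + seq_len(r)
    ixR <- length(xs) - r + seq_len(r)
    mask[ix, iyTop][cornerDrop(xs[ix], ys[iyTop], xs[r + 1], ys[r + 1])] <- FALSE
    mask[ixR, iyTop][cornerDrop(xs[ixR], ys[iyTop], xs[length(xs) - r], ys[r + 1])] <- FALSE
    mask[ix, iyBot][cornerDrop(xs[ix], ys[iyBot], xs[r + 1], ys[length(ys) - r])] <- FALSE
    mask[ixR, iyBot][cornerDrop(xs[ixR], ys[iyBot], xs[length(xs) - r], ys[length(ys) - r])] <- FALSE
    for (c in 1:3) {
      block <- img[xs, ys, c]
      block[mask] <- cfg$toothFill[c]
      img[xs, ys, c] <- block
    }
  }
  les <- layout$lesions
  if (!is.null(les)) for (i in seq_len(nrow(les))) {
    xs <- (les$xmin[i] + 1):les$xmax[i]
    ys <- (les$ymin[i] + 1):les$ymax[i]
    cx <- (les$xmin[i] + les$xmax[i] + 1) / 2
    cy <- (les$ymin[i] + les$ymax[i] + 1) / 2
    a <- (les$xmax[i] - les$xmin[i]) / 2
    b <- (les$ymax[i] - les$ymin[i]) / 2
    ell <- outer(((xs - cx) / a)^2, ((ys - cy) / b)^2, `+`) <= 1
    for (c in 1:3) {
      block <- img[xs, ys, c]
      block[ell] <- cfg$lesionFill[c]
      img[xs, ys, c] <- block
    }
  }
  if (cfg$noiseSd > 0) {
    noise <- matrix(rnorm(W * H, 0, cfg$noiseSd), W, H)
    for (c in 1:3) img[, , c] <- img[, , c] + noise
  }
  pmin(pmax(img, 0), 1)
}

.layoutRecord <- function(layout, id) {
  ann <- rbind(layout$teeth[c("xmin", "ymin", "xmax", "ymax", "label")],
               if (!is.null(layout$lesions))
                 layout$lesions[c("xmin", "ymin", "xmax", "ymax", "label")])
  rownames(ann) <- NULL
  ImageRecord(id, layout$width, layout$height, ann)
}

#' Generate a synthetic annotated dataset
#'
#' Deterministic given the config seed: the same seed yields byte-identical
#' label files. Optionally writes one PNG plus one YOLO-txt label file per
#' image and a `manifest.csv` (image_id, width, height) to `dir`; with a
#' `callback` each rendered image is handed over in memory instead of (or
#' in addition to) being written, which keeps large runs out of RAM and
#' off disk.
#'
#' @param cfg a [generatorConfig()].
#' @param nImages number of images (>= 1).
#' @param dir output directory, or `NULL` for no file output.
#' @param writeImages write PNGs (only with `dir`; label files and the
#'   manifest are always written when `dir` is given).
#' @param callback optional `function(image, record)` invoked per image
#'   with the rendered array and its [ImageRecord-class].
#' @param renderImages set `FALSE` to skip rendering entirely (labels
#'   only; much faster when only geometry is needed).
#' @return list with `records` (list of [ImageRecord-class]) and
#'   `manifest` (data.frame), invisibly carrying `dir`.
#' @export
generateDataset <- function(cfg, nImages, dir = NULL, writeImages = TRUE,
                            callback = NULL, renderImages = TRUE) {
  if (nImages < 1) stop("nImages must be >= 1")
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- vector("list", nImages)
  withLocalSeed(cfg$seed, {
    for (i in seq_len(nImages)) {
      id <- sprintf("synthetic_%04d", i)
      layout <- .sampleLayout(cfg)
      rec <- .layoutRecord(layout, id)
      records[[i]] <- rec
      img <- NULL
      if (renderImages && (!is.null(callback) ||
                           (!is.null(dir) && writeImages)))
        img <- .renderLayout(layout, cfg)
      if (!is.null(dir)) {
        writeYoloLabels(annotations(rec),
                        file.path(dir, paste0(id, ".txt")),
                        layout$width, layout$height)
        if (writeImages && !is.null(img))
          EBImage::writeImage(
            EBImage::Image(img, colormode = EBImage::Color),
            file.path(dir, paste0(id, ".png")))
      }
      if (!is.null(callback)) callback(img, rec)
    }
  })
  manifest <- data.frame(
    image_id = vapply(records, imageId, ""),
    width = vapply(records, function(r) imageDims(r)[["width"]], 0),
    height = vapply(records, function(r) imageDims(r)[["height"]], 0))
  if (!is.null(dir)) {
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    writeRunLog(dir, cfg, cfg$seed, list(nImages = nImages))
  }
  invisible(list(records = records, manifest = manifest, dir = dir))
}

#' Validate a generated dataset against the generator's invariants
#'
#' Checks that every annotation lies inside its image, that every lesion
#' box lies inside some tooth box of the same image, and (for >= 200
#' lesions) that the empirical median lesion area is within 20% of the
#' configured median.
#'
#' @param records list of [ImageRecord-class] objects.
#' @param cfg the [generatorConfig()] that produced them.
#' @return list with `ok`, `problems` (character, offending record ids
#'   with reasons), `nLesions`, `medianArea`, `configuredMedian`.
#' @export
datasetSelfCheck <- function(records, cfg) {
  problems <- character()
  areas <- numeric()
  for (rec in records) {
    ann <- annotations(rec)
    dims <- imageDims(rec)
    ok <- validateBoxes(ann, width = dims[["width"]],
                        height = dims[["height"]], stop. = FALSE)
    if (!isTRUE(ok))
      problems <- c(problems, paste0(imageId(rec), ": ", ok))
    teeth <- ann[ann$label == "tooth", , drop = FALSE]
    les <- ann[ann$label == "wsl", , drop = FALSE]
    if (nrow(les)) {
      areas <- c(areas, boxArea(les))
      for (j in seq_len(nrow(les))) {
        inside <- teeth$xmin <= les$xmin[j] & teeth$xmax >= les$xmax[j] &
          teeth$ymin <= les$ymin[j] & teeth$ymax >= les$ymax[j]
        if (!any(inside))
          problems <- c(problems, paste0(imageId(rec),
            ": lesion ", j, " outside every tooth box"))
      }
    }
  }
  med <- if (length(areas)) median(areas) else NA_real_
  if (length(areas) >= 200 &&
      abs(med - cfg$medianLesionArea) > 0.2 * cfg$medianLesionArea)
    problems <- c(problems, sprintf(
      "empirical median lesion area %.0f departs >20%% from configured %.0f",
      med, cfg$medianLesionArea))
  list(ok = length(problems) == 0L, problems = problems,
       nLesions = length(areas), medianArea = med,
       configuredMedian = cfg$medianLesionArea)
}
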