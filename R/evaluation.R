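# Accuracy metrics for box detection: greedy confidence-ordered matching,
# dataset-pooled precision-recall curves, COCO 101-point average
# precision, mAP over IoU 0.50-0.95, F1-over-IoU curves, pixel-wise
# Cohen's kappa on rasterized box masks, and percentile-bootstrap CIs.
# No ROC/AUC anywhere: true negatives are undefined for detection.

#' Greedy confidence-ordered detection matching
#'
#' Detections are visited by descending confidence; each is matched to the
#' unmatched ground truth of highest IoU, provided that IoU reaches
#' `iouThr`, otherwise it is a false positive. Matching is one-to-one;
#' unmatched ground truths are false negatives, so TP + FN equals the
#' number of ground truths.
#'
#' @param dets detection data.frame with `confidence`.
#' @param gts ground-truth box data.frame.
#' @param iouThr IoU threshold in (0, 1].
#' @return list with `tp` (logical per detection, in input row order),
#'   `assignment` (matched gt row index or NA, same order), and counts
#'   `TP`, `FP`, `FN`.
#' @export
matchDetections <- function(dets, gts, iouThr = 0.5) {
  nd <- if (is.null(dets)) 0L else nrow(dets)
  ng <- if (is.null(gts)) 0L else nrow(gts)
  tp <- logical(nd)
  assignment <- rep(NA_integer_, nd)
  if (nd > 0L && ng > 0L) {
    ord <- order(-dets$confidence)
    iou <- iouMatrix(dets, gts)
    gtFree <- rep(TRUE, ng)
    for (i in ord) {
      cand <- which(gtFree & iou[i, ] >= iouThr)
      if (length(cand)) {
        best <- cand[which.max(iou[i, cand])]
        gtFree[best] <- FALSE
        tp[i] <- TRUE
        assignment[i] <- best
      }
    }
  }
  list(tp = tp, assignment = assignment,
       TP = sum(tp), FP = nd - sum(tp), FN = ng - sum(tp))
}

#' Dataset-pooled precision-recall curve
#'
#' Matches per image at `iouThr`, then pools all detections across images
#' ranked by descending confidence and accumulates precision and recall as
#' the confidence cutoff sweeps down the ranking.
#'
#' @param predList named list of per-image detection data.frames.
#' @param gtList list of per-image ground-truth box data.frames (same
#'   order/names as `predList`).
#' @param iouThr IoU threshold for matching.
#' @return data.frame with columns `confidence`, `recall`, `precision`
#'   (one row per pooled detection; zero rows when there are none).
#' @export
prCurve <- function(predList, gtList, iouThr = 0.5) {
  stopifnot(length(predList) == length(gtList))
  flags <- list(); confs <- list()
  nGt <- 0L
  for (i in seq_along(predList)) {
    d <- predList[[i]]; g <- gtList[[i]]
    nGt <- nGt + if (is.null(g)) 0L else nrow(g)
    if (!is.null(d) && nrow(d)) {
      m <- matchDetections(d, g, iouThr)
      flags[[length(flags) + 1L]] <- m$tp
      confs[[length(confs) + 1L]] <- d$confidence
    }
  }
  tp <- unlist(flags); conf <- unlist(confs)
  if (length(tp) == 0L)
    return(data.frame(confidence = numeric(), recall = numeric(),
                      precision = numeric()))
  ord <- order(-conf)
  tp <- tp[ord]; conf <- conf[ord]
  cumTp <- cumsum(tp)
  data.frame(confidence = conf,
             recall = if (nGt > 0L) cumTp / nGt else rep(0, length(tp)),
             precision = cumTp / seq_along(tp))
}

#' COCO 101-point interpolated average precision
#'
#' The mean, over the recall grid 0, 0.01, ..., 1, of the maximum
#' precision attained at recall greater than or equal to each grid point
#' (the area under the interpolated precision-recall curve). An empty
#' curve gives 0.
#'
#' @param pr a [prCurve()] data.frame.
#' @return AP in \[0, 1\].
#' @export
averagePrecision <- function(pr) {
  if (nrow(pr) == 0L) return(0)
  ord <- order(pr$recall, -pr$precision)
  rec <- pr$recall[ord]
  # envelope: max precision at recall >= r, via right-to-left running max
  prec <- rev(cummax(rev(pr$precision[ord])))
  grid <- seq(0, 1, by = 0.01)
  idx <- findInterval(grid, rec, left.open = TRUE) + 1L  # first rec >= g
  vals <- ifelse(idx <= length(rec), prec[pmin(idx, length(rec))], 0)
  mean(vals)
}

#' Average precision at one IoU threshold
#'
#' @inheritParams prCurve
#' @return AP in \[0, 1\].
#' @export
apAt <- function(predList, gtList, iouThr = 0.5) {
  averagePrecision(prCurve(predList, gtList, iouThr))
}

#' Mean average precision over an IoU threshold range
#'
#' Arithmetic mean of [apAt()] over the thresholds (COCO convention:
#' 0.50 to 0.95 in steps of 0.05). Always bounded above by AP at the
#' lowest threshold.
#'
#' @inheritParams prCurve
#' @param thresholds IoU thresholds to average over.
#' @return mAP in \[0, 1\].
#' @export
mapRange <- function(predList, gtList, thresholds = round(seq(0.5, 0.95, by = 0.05), 2)) {
  mean(vapply(thresholds, function(t) apAt(predList, gtList, t), numeric(1)))
}

.countsAt <- function(predList, gtList, iouThr, cutoff) {
  TP <- 0L; FP <- 0L; FN <- 0L
  for (i in seq_along(predList)) {
    d <- predList[[i]]
    if (!is.null(d) && nrow(d))
      d <- d[d$confidence >= cutoff, , drop = FALSE]
    m <- matchDetections(d, gtList[[i]], iouThr)
    TP <- TP + m$TP; FP <- FP + m$FP; FN <- FN + m$FN
  }
  c(TP = TP, FP = FP, FN = FN)
}

#' TP/FN/FP counts at a confidence cutoff
#'
#' @inheritParams prCurve
#' @param cutoff confidence cutoff; detections below it are discarded.
#' @return named integer vector `TP`, `FP`, `FN`.
#' @export
countsAtCutoff <- function(predList, gtList, iouThr = 0.5, cutoff = 0) {
  .countsAt(predList, gtList, iouThr, cutoff)
}

.f1 <- function(counts) {
  P <- if (counts["TP"] + counts["FP"] > 0)
    counts["TP"] / (counts["TP"] + counts["FP"]) else 0
  R <- if (counts["TP"] + counts["FN"] > 0)
    counts["TP"] / (counts["TP"] + counts["FN"]) else 0
  if (P + R == 0) return(c(F1 = 0, P = unname(P), R = unname(R)))
  c(F1 = unname(2 * P * R / (P + R)), P = unname(P), R = unname(R))
}

#' Confidence cutoff maximizing F1 at a given IoU threshold
#'
#' Scans the distinct pooled confidences; ties resolved toward the higher
#' cutoff (fewer reported boxes). Used as the operating point for counts
#' and F1 curves since detection counts are cutoff-dependent.
#'
#' @inheritParams prCurve
#' @return the cutoff (0 when there are no detections).
#' @export
bestF1Cutoff <- function(predList, gtList, iouThr = 0.5) {
  confs <- sort(unique(unlist(lapply(predList, function(d)
    if (is.null(d)) numeric() else d$confidence))), decreasing = TRUE)
  if (length(confs) == 0L) return(0)
  f1s <- vapply(confs, function(ct)
    .f1(.countsAt(predList, gtList, iouThr, ct))["F1"], numeric(1))
  confs[which.max(f1s)]
}

#' F1 score over a range of IoU thresholds
#'
#' Evaluates F1 = 2PR / (P + R) at each IoU threshold at a fixed operating
#' confidence cutoff (by default the cutoff maximizing F1 at IoU 0.5).
#' F1 is 0 when P + R = 0.
#'
#' @inheritParams prCurve
#' @param thresholds IoU thresholds for the curve.
#' @param cutoff operating confidence cutoff, or `NULL` to pick
#'   [bestF1Cutoff()] at IoU 0.5.
#' @return data.frame with columns `iou`, `f1`, `precision`, `recall` and
#'   attribute `cutoff`.
#' @export
f1OverIou <- function(predList, gtList,
                      thresholds = round(seq(0.5, 0.95, by = 0.05), 2),
                      cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- bestF1Cutoff(predList, gtList, 0.5)
  rows <- t(vapply(thresholds, function(t)
    .f1(.countsAt(predList, gtList, t, cutoff)), numeric(3)))
  structure(data.frame(iou = thresholds, f1 = rows[, "F1"],
                       precision = rows[, "P"], recall = rows[, "R"]),
            cutoff = cutoff)
}

#' Pixel-wise Cohen's kappa between two box sets
#'
#' Each image's predicted and ground-truth box sets are rasterized (at the
#' original image resolution) into binary masks; the 2x2 pixel confusion
#' matrix is accumulated over all images (pooled, the default) and kappa
#' is `(p_o - p_e) / (1 - p_e)` with marginal-product expected agreement.
#' Measures agreement about lesion *boundaries*, the primary metric of the
#' evaluation suite. When both raters are constant (`p_e = 1`) kappa is
#' undefined and an error is signaled.
#'
#' @param predList list of per-image predicted box data.frames (original
#'   frame).
#' @param gtList list of per-image ground-truth box data.frames.
#' @param dims data.frame with columns `width`, `height` (one row per
#'   image, same order).
#' @param pooled pool confusion matrices across images (default); when
#'   `FALSE`, per-image kappas are averaged (undefined images dropped).
#' @return kappa in \[-1, 1\].
#' @export
pixelKappa <- function(predList, gtList, dims, pooled = TRUE) {
  stopifnot(length(predList) == length(gtList),
            nrow(dims) == length(predList))
  kap <- function(cm) {
    n <- sum(cm)
    po <- (cm[1] + cm[4]) / n
    pe <- ((cm[1] + cm[2]) * (cm[1] + cm[3]) +
           (cm[3] + cm[4]) * (cm[2] + cm[4])) / n^2
    if (1 - pe == 0)
      stop("kappa undefined: both raters are constant (p_e = 1)",
           call. = FALSE)
    (po - pe) / (1 - pe)
  }
  cms <- lapply(seq_along(predList), function(i) {
    w <- dims$width[i]; h <- dims$height[i]
    p <- rasterizeBoxes(predList[[i]], w, h)
    g <- rasterizeBoxes(gtList[[i]], w, h)
    both <- sum(p & g)
    # order: (both, pred-only, gt-only, neither)
    c(both, sum(p) - both, sum(g) - both,
      as.numeric(w) * h - sum(p) - sum(g) + both)
  })
  if (pooled) return(kap(Reduce(`+`, cms)))
  ks <- vapply(cms, function(cm) tryCatch(kap(cm), error = function(e) NA_real_),
               numeric(1))
  mean(ks, na.rm = TRUE)
}

#' Percentile bootstrap confidence interval over images
#'
#' Resamples images with replacement `nBoot` times, recomputes the metric
#' on each resample, and reports the 2.5% and 97.5% percentiles plus the
#' resample median. Seeded and reproducible; the global RNG state is
#' restored on exit.
#'
#' @param statistic function `(predList, gtList, imageIdx)` returning a
#'   scalar; `imageIdx` gives the resampled image indices so dimension
#'   tables can be subset alongside.
#' @param predList,gtList per-image lists passed through to `statistic`
#'   already subset to the resample.
#' @param nBoot number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return named numeric vector `lo`, `hi`, `median`.
#' @export
bootstrapCI <- function(statistic, predList, gtList, nBoot = 1000L,
                        seed = 1L, level = 0.95) {
  n <- length(predList)
  stopifnot(n == length(gtList), n >= 1L)
  vals <- withLocalSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      statistic(predList[idx], gtList[idx], idx)
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- quantile(vals, c(a, 0.5, 1 - a), names = FALSE, type = 7)
  c(lo = q[1], hi = q[3], median = q[2])
}

#' Full dataset-level evaluation report
#'
#' Computes every accuracy quantity of the evaluation suite for one
#' detector arm: pooled pixel kappa, AP@0.5, mAP@0.5:0.95, the F1-over-IoU
#' curve, and TP/FN/FP at the operating cutoff, optionally with bootstrap
#' 95% confidence intervals for kappa, AP@0.5 and mAP.
#'
#' @inheritParams pixelKappa
#' @param nBoot bootstrap resamples for CIs; 0 disables CIs.
#' @param seed bootstrap seed.
#' @return an [EvaluationReport-class].
#' @export
evaluateDetections <- function(predList, gtList, dims, nBoot = 0L, seed = 1L) {
  cutoff <- bestF1Cutoff(predList, gtList, 0.5)
  counts <- .countsAt(predList, gtList, 0.5, cutoff)
  prf <- .f1(counts)
  ci <- list()
  if (nBoot > 0L) {
    ci <- list(
      kappa = bootstrapCI(function(p, g, idx)
        pixelKappa(p, g, dims[idx, , drop = FALSE]),
        predList, gtList, nBoot, seed),
      ap50 = bootstrapCI(function(p, g, idx) apAt(p, g, 0.5),
                         predList, gtList, nBoot, seed),
      map = bootstrapCI(function(p, g, idx) mapRange(p, g),
                        predList, gtList, nBoot, seed))
  }
  f1c <- f1OverIou(predList, gtList, cutoff = cutoff)
  new("EvaluationReport",
      kappa = pixelKappa(predList, gtList, dims),
      ap50 = apAt(predList, gtList, 0.5),
      map = mapRange(predList, gtList),
      f1Curve = f1c,
      tp = as.integer(counts["TP"]), fn = as.integer(counts["FN"]),
      fp = as.integer(counts["FP"]),
      precision = prf["P"], recall = prf["R"], cutoff = cutoff, ci = ci)
}

setMethod("show", "EvaluationReport", function(object) {
  fmt <- function(x) sprintf("%.4f", x)
  cat("EvaluationReport\n",
      "  pixel kappa:   ", fmt(object@kappa), "\n",
      "  AP@0.5:        ", fmt(object@ap50), "\n",
      "  mAP@0.5:0.95:  ", fmt(object@map), "\n",
      sprintf("  TP/FN/FP:       %d/%d/%d at cutoff %.3f (P %.3f, R %.3f)\n",
              object@tp, object@fn, object@fp, object@cutoff,
              object@precision, object@recall), sep = "")
  for (nm in names(object@ci))
    cat(sprintf("  95%% CI %-6s [%.4f, %.4f]\n", paste0(nm, ":"),
                object@ci[[nm]]["lo"], object@ci[[nm]]["hi"]))
})
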