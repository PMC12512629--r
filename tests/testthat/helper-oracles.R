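# Independent oracles and fixture builders. Each oracle is a separate,
# deliberately naive code path from the implementation it checks.

# random integer boxes inside a W x H frame (draws from the current RNG)
randomBoxes <- function(n, W = 100, H = 100, maxSide = 40, conf = TRUE) {
  x0 <- sample.int(W - 2, n, replace = TRUE) - 1
  y0 <- sample.int(H - 2, n, replace = TRUE) - 1
  w <- pmin(sample.int(maxSide, n, replace = TRUE), W - x0 - 1) + 1
  h <- pmin(sample.int(maxSide, n, replace = TRUE), H - y0 - 1) + 1
  wslBoxes(x0, y0, x0 + w, y0 + h, label = "wsl",
           confidence = if (conf) round(runif(n), 3) else NULL)
}

# pixel-counting IoU for integer boxes (oracle for the closed form)
maskIoU <- function(a, b, W = 200, H = 200) {
  ma <- rasterizeBoxes(a, W, H)
  mb <- rasterizeBoxes(b, W, H)
  sum(ma & mb) / sum(ma | mb)
}

# naive quadratic greedy NMS, strict ">" suppression, stable ties
bruteNms <- function(dets, thr) {
  ord <- order(-dets$confidence)
  d <- dets[ord, , drop = FALSE]
  kept <- d[0, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    suppressed <- FALSE
    for (j in seq_len(nrow(kept)))
      if (boxIoU(d[i, , drop = FALSE], kept[j, , drop = FALSE]) > thr)
        suppressed <- TRUE
    if (!suppressed) kept <- rbind(kept, d[i, , drop = FALSE])
  }
  rownames(kept) <- NULL
  kept
}

# naive greedy matching (independent of matchDetections)
bruteMatch <- function(dets, gts, thr) {
  used <- rep(FALSE, nrow(gts))
  tp <- 0L
  if (nrow(dets)) for (i in order(-dets$confidence)) {
    best <- 0; bestJ <- 0L
    for (j in seq_len(nrow(gts))) {
      if (used[j]) next
      v <- boxIoU(dets[i, , drop = FALSE], gts[j, , drop = FALSE])
      if (v >= thr && v > best) { best <- v; bestJ <- j }
    }
    if (bestJ > 0L) { used[bestJ] <- TRUE; tp <- tp + 1L }
  }
  c(TP = tp, FP = nrow(dets) - tp, FN = nrow(gts) - tp)
}

# brute-force 101-point AP: walk the pooled confidence ranking one
# detection at a time (the operating points of the cumulative PR curve),
# recomputing every prefix's TP count from scratch with the naive
# matcher, then scan the whole point set for the max precision at
# recall >= each grid value. Greedy confidence-ordered matching of a
# ranking prefix equals the full matching restricted to that prefix, so
# per-prefix rematching is a valid independent route.
bruteAP <- function(predList, gtList, thr) {
  conf <- unlist(lapply(predList, function(d) d$confidence))
  img <- rep(seq_along(predList),
             vapply(predList, function(d) if (is.null(d)) 0L else nrow(d), 0L))
  row <- unlist(lapply(predList, function(d) seq_len(nrow(d))))
  nGt <- sum(vapply(gtList, nrow, 0L))
  if (length(conf) == 0L) return(0)
  ord <- order(-conf)  # stable: ties keep pooling order, as in prCurve
  pts <- t(vapply(seq_along(ord), function(k) {
    take <- ord[seq_len(k)]
    tp <- 0L
    for (i in unique(img[take])) {
      d <- predList[[i]][row[take][img[take] == i], , drop = FALSE]
      tp <- tp + bruteMatch(d, gtList[[i]], thr)[["TP"]]
    }
    c(R = if (nGt) tp / nGt else 0, P = tp / k)
  }, numeric(2)))
  mean(vapply(seq(0, 1, 0.01), function(g) {
    ok <- pts[, "R"] >= g
    if (any(ok)) max(pts[ok, "P"]) else 0
  }, numeric(1)))
}

# a tiny random detection scenario: per-image gts plus jittered/extra dets
randomScenario <- function(nImages = 3, maxGt = 4) {
  gts <- list(); preds <- list()
  for (i in seq_len(nImages)) {
    ng <- sample.int(maxGt + 1, 1) - 1L
    g <- if (ng) randomBoxes(ng, conf = FALSE) else
      wslBoxes(numeric(), numeric(), numeric(), numeric())
    d <- if (ng) {
      jit <- g
      sh <- sample(0:6, ng, replace = TRUE)
      jit$xmin <- jit$xmin + sh; jit$xmax <- jit$xmax + sh
      jit$confidence <- round(runif(ng), 3)
      jit$label <- "wsl"
      keep <- runif(ng) < 0.8
      rbind(jit[keep, , drop = FALSE], randomBoxes(sample.int(3, 1)))
    } else randomBoxes(sample.int(2, 1))
    gts[[i]] <- g; preds[[i]] <- d
  }
  list(preds = preds, gts = gts)
}

# rasterized oracle for rectangle-union area (integer boxes)
bruteUnionArea <- function(boxes, W = 200, H = 200) {
  sum(rasterizeBoxes(boxes, W, H))
}

# deterministic synthetic scene for pipeline traces: a fit-sized canvas
# (scale 1, so no resize rounding) with one dim "tooth" rectangle and
# optional bright "lesion" rectangles
traceScene <- function(tooth = c(50, 50, 600, 600), lesions = NULL,
                       size = 640) {
  img <- matrix(0, size, size)
  img[(tooth[1] + 1):tooth[3], (tooth[2] + 1):tooth[4]] <- 0.6
  if (!is.null(lesions)) for (i in seq_len(nrow(lesions)))
    img[(lesions$xmin[i] + 1):lesions$xmax[i],
        (lesions$ymin[i] + 1):lesions$ymax[i]] <- 1
  img
}

traceDetectors <- function() {
  list(tooth = blobDetector("tooth", threshold = 0.5, minArea = 500),
       wsl = blobDetector("wsl", threshold = 0.8, minArea = 16))
}
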