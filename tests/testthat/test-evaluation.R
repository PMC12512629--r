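test_that("greedy matching is one-to-one and conserves ground truths", {
  gt <- wslBoxes(0, 0, 10, 10)
  hit <- wslBoxes(0, 0, 10, 10, label = "wsl", confidence = 0.9)
  m <- matchDetections(hit, gt, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(1L, 0L, 0L))

  # two detections over one gt: only the more confident one matches
  two <- wslBoxes(c(0, 1), c(0, 0), c(10, 11), c(10, 10), label = "wsl",
                  confidence = c(0.9, 0.8))
  m2 <- matchDetections(two, gt, 0.5)
  expect_equal(c(m2$TP, m2$FP), c(1L, 1L))
  expect_true(m2$tp[1]); expect_false(m2$tp[2])

  m3 <- matchDetections(two[0, ], wslBoxes(c(0, 20, 40), c(0, 0, 0),
                                           c(10, 30, 50), c(10, 10, 10)), 0.5)
  expect_equal(m3$FN, 3L)

  # TP + FN = #gts at every threshold, against the brute-force oracle
  set.seed(13)
  for (rep in 1:20) {
    sc <- randomScenario(1)
    thr <- sample(seq(0.3, 0.9, 0.1), 1)
    m <- matchDetections(sc$preds[[1]], sc$gts[[1]], thr)
    expect_equal(m$TP + m$FN, nrow(sc$gts[[1]]))
    expect_equal(c(TP = m$TP, FP = m$FP, FN = m$FN),
                 bruteMatch(sc$preds[[1]], sc$gts[[1]], thr))
  }
})

test_that("PR curves accumulate pooled cumulative precision and recall", {
  gts <- list(wslBoxes(c(0, 100), c(0, 0), c(10, 110), c(10, 10)))
  # ranking TP, FP, TP over 2 ground truths
  dets <- list(wslBoxes(c(0, 50, 100), c(0, 0, 0), c(10, 60, 110),
                        c(10, 10, 10), label = "wsl",
                        confidence = c(0.9, 0.8, 0.7)))
  pr <- prCurve(dets, gts, 0.5)
  expect_equal(pr$recall, c(0.5, 0.5, 1))
  expect_equal(pr$precision, c(1, 0.5, 2 / 3))
  expect_equal(averagePrecision(pr), (51 + 50 * 2 / 3) / 101)

  # perfect detector: single point (1, 1), AP 1
  perfect <- list(wslBoxes(c(0, 100), c(0, 0), c(10, 110), c(10, 10),
                           label = "wsl", confidence = c(0.9, 0.8)))
  prp <- prCurve(perfect, gts, 0.5)
  expect_equal(prp$recall[nrow(prp)], 1)
  expect_equal(prp$precision, c(1, 1))
  expect_equal(averagePrecision(prp), 1)

  # no detections: empty curve, AP 0
  none <- list(dets[[1]][0, ])
  expect_equal(nrow(prCurve(none, gts, 0.5)), 0L)
  expect_equal(averagePrecision(prCurve(none, gts, 0.5)), 0)
})

test_that("AP and mAP agree with the brute-force oracle on random instances", {
  set.seed(99)
  for (rep in 1:30) {
    sc <- randomScenario(sample(1:3, 1))
    expect_equal(apAt(sc$preds, sc$gts, 0.5), bruteAP(sc$preds, sc$gts, 0.5),
                 tolerance = 1e-9)
    thresholds <- seq(0.5, 0.95, 0.05)
    expect_equal(mapRange(sc$preds, sc$gts),
                 mean(vapply(thresholds, function(t)
                   bruteAP(sc$preds, sc$gts, t), numeric(1))),
                 tolerance = 1e-9)
    # mean over thresholds never exceeds AP at the lowest threshold
    expect_lte(mapRange(sc$preds, sc$gts), apAt(sc$preds, sc$gts, 0.5) + 1e-12)
  }
})

test_that("mAP over thresholds counts exactly the thresholds an IoU clears", {
  # detections with IoU exactly 0.7 against every gt: AP 1 up to 0.7, 0 above
  gts <- list(wslBoxes(c(0, 50), c(0, 0), c(10, 60), c(10, 10)))
  dets <- list(wslBoxes(c(0, 50), c(0, 0), c(10, 60), c(7, 7), label = "wsl",
                        confidence = c(0.9, 0.8)))
  expect_equal(boxIoU(dets[[1]][1, ], gts[[1]][1, ]), 0.7)
  expect_equal(apAt(dets, gts, 0.70), 1)
  expect_equal(apAt(dets, gts, 0.75), 0)
  expect_equal(mapRange(dets, gts), 0.5)
})

test_that("F1 curves use the operating cutoff and fall with IoU threshold", {
  # 2 gts, one exact hit and one far miss at the cutoff: P = R = 0.5, F1 0.5
  gts <- list(wslBoxes(c(0, 100), c(0, 0), c(10, 110), c(10, 10)))
  dets <- list(wslBoxes(c(0, 200), c(0, 200), c(10, 210), c(10, 210),
                        label = "wsl", confidence = c(0.9, 0.8)))
  f1c <- f1OverIou(dets, gts, thresholds = 0.5, cutoff = 0)
  expect_equal(f1c$f1, 0.5)
  expect_equal(f1c$precision, 0.5)
  expect_equal(f1c$recall, 0.5)

  # perfect detector: F1 = 1 along the curve until geometry breaks
  perfect <- list(wslBoxes(c(0, 100), c(0, 0), c(10, 110), c(10, 10),
                           label = "wsl", confidence = c(0.9, 0.8)))
  f1p <- f1OverIou(perfect, gts)
  expect_true(all(f1p$f1 == 1))

  # monotone non-increasing in the IoU threshold at a fixed cutoff
  set.seed(7)
  for (rep in 1:15) {
    sc <- randomScenario(2)
    f1 <- f1OverIou(sc$preds, sc$gts, cutoff = 0)$f1
    expect_true(all(diff(f1) <= 1e-12))
  }
})

test_that("pixel kappa reproduces the hand confusion-matrix example", {
  dims <- data.frame(width = 10, height = 10)
  gt <- list(wslBoxes(0, 0, 10, 2))   # 20 px
  pd <- list(wslBoxes(0, 1, 10, 3))   # 20 px, 10 px overlap
  # p_o = 0.8, p_e = 0.68, kappa = 0.12 / 0.32
  expect_equal(pixelKappa(pd, gt, dims), 0.375)

  expect_equal(pixelKappa(gt, gt, dims), 1)           # identity
  all100 <- list(wslBoxes(0, 0, 10, 10))
  expect_equal(pixelKappa(all100, gt, dims), 0)       # constant rater
  none <- list(gt[[1]][0, ])
  expect_error(pixelKappa(none, none, dims), "undefined")

  # symmetry and joint translation invariance
  set.seed(8)
  for (rep in 1:10) {
    a <- list(randomBoxes(3, W = 60, H = 60, conf = FALSE))
    b <- list(randomBoxes(2, W = 60, H = 60, conf = FALSE))
    d <- data.frame(width = 100, height = 100)
    expect_equal(pixelKappa(a, b, d), pixelKappa(b, a, d))
    shift <- function(l) list(toOriginal(l[[1]], c(15, 20)))
    expect_equal(pixelKappa(shift(a), shift(b), d), pixelKappa(a, b, d))
  }
})

test_that("bootstrap CIs are seeded, degenerate for constants, and cover the estimate", {
  sc <- withr::with_seed(4, randomScenario(12))
  dims <- data.frame(width = rep(100, 12), height = rep(100, 12))

  constCI <- bootstrapCI(function(p, g, idx) 0.42, sc$preds, sc$gts,
                         nBoot = 50, seed = 1)
  expect_equal(unname(constCI), c(0.42, 0.42, 0.42))

  ci1 <- bootstrapCI(function(p, g, idx) apAt(p, g, 0.5), sc$preds, sc$gts,
                     nBoot = 200, seed = 7)
  ci2 <- bootstrapCI(function(p, g, idx) apAt(p, g, 0.5), sc$preds, sc$gts,
                     nBoot = 200, seed = 7)
  expect_identical(ci1, ci2)
  point <- apAt(sc$preds, sc$gts, 0.5)
  expect_lte(ci1[["lo"]], point)
  expect_gte(ci1[["hi"]], point)
})

test_that("the full report ties the metrics together consistently", {
  sc <- withr::with_seed(14, randomScenario(8))
  dims <- data.frame(width = rep(100, 8), height = rep(100, 8))
  rep. <- evaluateDetections(sc$preds, sc$gts, dims, nBoot = 50, seed = 2)
  expect_s4_class(rep., "EvaluationReport")
  expect_lte(rep.@map, rep.@ap50 + 1e-12)
  nGt <- sum(vapply(sc$gts, nrow, 0L))
  expect_equal(rep.@tp + rep.@fn, nGt)
  if (rep.@tp + rep.@fp > 0)
    expect_equal(rep.@precision, rep.@tp / (rep.@tp + rep.@fp),
                 ignore_attr = TRUE)
  expect_equal(rep.@recall, rep.@tp / (rep.@tp + rep.@fn),
               ignore_attr = TRUE)
  expect_named(rep.@ci, c("kappa", "ap50", "map"))
})
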