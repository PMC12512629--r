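test_that("area statistics use type-7 quantiles and COCO size classes", {
  three <- wslBoxes(c(0, 0, 0), c(0, 0, 0), c(10, 40, 100), c(10, 50, 100))
  s <- areaStats(three)  # areas 100, 2000, 10000
  expect_equal(unname(s@counts), c(1L, 1L, 1L))
  expect_equal(names(s@counts), c("small", "medium", "large"))

  one <- areaStats(three[2, , drop = FALSE])
  expect_equal(c(one@q1, one@median, one@q3), c(2000, 2000, 2000))

  four <- wslBoxes(rep(0, 4), rep(0, 4), c(1, 2, 3, 4), rep(1, 4))
  expect_equal(areaStats(four)@median, 2.5)

  # the printed small-size cutoff is a half-open boundary at 1024 px
  expect_equal(as.character(cocoSizeClass(c(1023, 1024, 9215, 9216))),
               c("small", "medium", "medium", "large"))
})

test_that("downscaling shifts areas by scale squared and inflates the small class", {
  rt <- proportionalResize(4000, 3000, 640)  # scale 0.16
  b <- wslBoxes(0, 0, 2898 / 54, 54)          # area 2898
  shift <- downscaleShift(b, rt)
  expect_equal(shift$before@median, 2898, tolerance = 1e-9)
  expect_equal(shift$after@median, 2898 * 0.16^2, tolerance = 1e-9)
  expect_equal(as.character(cocoSizeClass(shift$after@median)), "small")

  ident <- proportionalResize(640, 640, 640)
  same <- downscaleShift(b, ident)
  expect_equal(same$before@median, same$after@median)

  # proportion of small boxes is non-decreasing under any scale < 1
  set.seed(61)
  boxes <- randomBoxes(200, W = 4000, H = 3000, maxSide = 200, conf = FALSE)
  for (scale in c(0.9, 0.5, 0.16)) {
    sh <- downscaleShift(boxes, proportionalResize(4000, 3000, 4000 * scale))
    expect_gte(sh$after@counts[["small"]], sh$before@counts[["small"]])
  }
})

test_that("the 2x2 chi-square matches the textbook statistic", {
  expect_equal(chiSquare2x2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  balanced <- chiSquare2x2(matrix(c(20, 0, 0, 20), 2))
  expect_equal(balanced$statistic, 40)
  expect_lt(balanced$p.value, 0.001)
  expect_error(chiSquare2x2(matrix(c(0, 0, 5, 5), 2)), "expected")

  set.seed(33)
  for (rep in 1:25) {
    tab <- matrix(sample(1:200, 4, replace = TRUE), 2)
    ours <- chiSquare2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("absolute heatmaps conserve normalized box mass", {
  full <- wslBoxes(0, 0, 100, 80)
  hm <- absoluteHeatmap(full, 100, 80, gridSize = 16)
  expect_true(all(abs(hm@grid - 1) < 1e-12))  # full-frame box: uniform 1

  none <- absoluteHeatmap(full[0, ], 100, 80, gridSize = 16)
  expect_true(all(none@grid == 0))

  set.seed(44)
  boxes <- randomBoxes(20, W = 200, H = 150, conf = FALSE)
  hm2 <- absoluteHeatmap(boxes, 200, 150, gridSize = 32)
  expect_equal(sum(hm2@grid), sum(boxArea(boxes) / (200 * 150)) * 32^2,
               tolerance = 1e-9)
})

test_that("relative heatmaps express lesions in the host tooth's unit square", {
  tooth <- wslBoxes(100, 200, 200, 400)
  lesion <- wslBoxes(150, 380, 170, 400)  # unit square x [0.5,0.7], y [0.9,1]
  hm <- relativeHeatmap(list(lesion), list(tooth), gridSize = 10)
  nz <- which(hm@grid > 0, arr.ind = TRUE)
  expect_equal(sort(unique(nz[, 1])), 6:7)    # x cells for [0.5, 0.7]
  expect_equal(sort(unique(nz[, 2])), 10L)    # y cell for [0.9, 1.0]
  expect_equal(hm@dropped, 0L)

  # lesion identical to its tooth fills the unit square uniformly
  hmFull <- relativeHeatmap(list(tooth), list(tooth), gridSize = 8)
  expect_true(all(abs(hmFull@grid - 1) < 1e-12))

  # lesions disjoint from every tooth are dropped and tallied
  far <- wslBoxes(1000, 1000, 1020, 1020)
  hmDrop <- relativeHeatmap(list(rbind(lesion, far)), list(tooth))
  expect_equal(hmDrop@dropped, 1L)
})

test_that("generated lesions concentrate in the peripheral band", {
  cfg <- generatorConfig(imageWidth = 1600, imageHeight = 1200, seed = 55)
  out <- generateDataset(cfg, 25, renderImages = FALSE)
  lesionList <- lapply(out$records, function(r) {
    a <- annotations(r); a[a$label == "wsl", , drop = FALSE]
  })
  toothList <- lapply(out$records, function(r) {
    a <- annotations(r); a[a$label == "tooth", , drop = FALSE]
  })
  hm <- relativeHeatmap(lesionList, toothList)
  periph <- peripheralMassFraction(hm)
  expect_gt(periph, 0.5)  # peripheral band outweighs the central region
})

test_that("crown coverage is the exact union fraction inside the tooth", {
  tooth <- wslBoxes(0, 0, 100, 100)
  expect_equal(crownCoverage(tooth, tooth), 1)

  two <- wslBoxes(c(10, 50), c(10, 50), c(20, 60), c(20, 60))
  expect_equal(crownCoverage(two, tooth), 0.02)

  # fully overlapping lesions are counted once
  dup <- wslBoxes(c(10, 10), c(10, 10), c(20, 20), c(20, 20))
  expect_equal(crownCoverage(dup, tooth), 0.01)

  # clipped to the tooth: mass outside does not count
  hang <- wslBoxes(90, 90, 120, 120)
  expect_equal(crownCoverage(hang, tooth), 0.01)

  expect_equal(crownCoverage(two[0, ], tooth), 0)

  set.seed(77)
  for (rep in 1:15) {
    boxes <- randomBoxes(sample(1:8, 1), W = 200, H = 200, conf = FALSE)
    expect_equal(rectUnionArea(boxes), bruteUnionArea(boxes))
  }
})
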