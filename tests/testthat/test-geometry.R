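test_that("IoU handles identity, partial overlap, and disjoint boxes", {
  a <- wslBoxes(0, 0, 10, 10)
  expect_equal(boxIoU(a, a), 1)
  expect_equal(boxIoU(a, wslBoxes(5, 0, 15, 10)), 1 / 3)
  expect_equal(boxIoU(a, wslBoxes(20, 20, 30, 30)), 0)
  expect_error(wslBoxes(0, 0, 0, 10), "degenerate")
  expect_error(boxIoU(a, data.frame(xmin = 0, ymin = 0, xmax = 0, ymax = 5)),
               "degenerate")
})

test_that("IoU is symmetric, translation invariant, and matches pixel counting", {
  set.seed(11)
  for (rep in 1:30) {
    a <- randomBoxes(1, conf = FALSE)
    b <- randomBoxes(1, conf = FALSE)
    expect_equal(boxIoU(a, b), boxIoU(b, a))
    sh <- function(x, dx, dy) {
      x$xmin <- x$xmin + dx; x$xmax <- x$xmax + dx
      x$ymin <- x$ymin + dy; x$ymax <- x$ymax + dy; x
    }
    expect_equal(boxIoU(sh(a, 7, 3), sh(b, 7, 3)), boxIoU(a, b))
    expect_equal(boxIoU(a, b), maskIoU(a, b), tolerance = 1e-12)
  }
})

test_that("iouMatrix agrees with pairwise IoU", {
  set.seed(5)
  a <- randomBoxes(6, conf = FALSE)
  b <- randomBoxes(4, conf = FALSE)
  m <- iouMatrix(a, b)
  for (i in 1:6) for (j in 1:4)
    expect_equal(m[i, j],
                 boxIoU(a[i, , drop = FALSE], b[j, , drop = FALSE]))
})

test_that("NMS suppresses direct overlaps and keeps chain survivors", {
  # two heavily overlapping boxes: only the more confident one survives
  two <- wslBoxes(c(0, 1), c(0, 0), c(10, 11), c(10, 10), label = "wsl",
                  confidence = c(0.9, 0.7))
  expect_gt(boxIoU(two[1, ], two[2, ]), 0.5)
  kept <- nms(two, 0.5)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$confidence, 0.9)

  # chain: B suppressed by A; C overlaps only the suppressed B, so it stays
  chain <- wslBoxes(c(0, 3, 6), c(0, 0, 0), c(10, 13, 16), c(10, 10, 10),
                    label = "wsl", confidence = c(0.9, 0.8, 0.7))
  expect_gt(boxIoU(chain[1, ], chain[2, ]), 0.5)
  expect_gt(boxIoU(chain[2, ], chain[3, ]), 0.5)
  expect_lte(boxIoU(chain[1, ], chain[3, ]), 0.5)
  kept <- nms(chain, 0.5)
  expect_equal(kept$confidence, c(0.9, 0.7))

  single <- two[1, , drop = FALSE]
  expect_equal(nms(single, 0.5), single, ignore_attr = TRUE)
  empty <- two[0, , drop = FALSE]
  expect_equal(nrow(nms(empty, 0.5)), 0L)
})

test_that("NMS is idempotent, bounds survivor overlaps, and matches brute force", {
  set.seed(42)
  for (rep in 1:25) {
    d <- randomBoxes(sample(2:12, 1))
    thr <- runif(1, 0.2, 0.8)
    kept <- nms(d, thr)
    # survivors are a subset in confidence order, top detection always kept
    expect_true(all(kept$confidence == sort(kept$confidence,
                                            decreasing = TRUE)))
    expect_true(max(d$confidence) %in% kept$confidence)
    # idempotence
    expect_equal(nms(kept, thr), kept)
    # pairwise IoU bound among survivors
    if (nrow(kept) > 1) {
      m <- iouMatrix(kept, kept)
      expect_lte(max(m[upper.tri(m)]), thr)
    }
    expect_equal(kept, bruteNms(d, thr))
  }
})

test_that("ImageRecord validates annotations against its frame", {
  rec <- ImageRecord("img1", 100, 80,
                     wslBoxes(c(0, 50), c(0, 10), c(20, 90), c(20, 70),
                              label = c("tooth", "wsl")))
  expect_equal(imageId(rec), "img1")
  expect_equal(unname(imageDims(rec)), c(100, 80))
  expect_equal(nrow(annotations(rec)), 2L)
  expect_error(ImageRecord("bad", 100, 80, wslBoxes(0, 0, 120, 20,
                                                    label = "tooth")),
               "width")
})
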