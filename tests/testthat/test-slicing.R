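test_that("proportional resize keeps aspect ratio without padding", {
  rt <- proportionalResize(4000, 3000, 640)
  expect_equal(rt@scale, 0.16)
  expect_equal(rt@targetSize, c(640L, 480L))

  rt1 <- proportionalResize(640, 640, 640)
  expect_equal(rt1@scale, 1)
  expect_equal(rt1@targetSize, c(640L, 640L))

  # upscaling is permitted
  rt2 <- proportionalResize(300, 600, 640)
  expect_equal(rt2@scale, 640 / 600)
  expect_equal(rt2@targetSize, c(320L, 640L))

  expect_error(proportionalResize(0, 100, 640), "positive")
})

test_that("box rescaling is exact on the worked example and bounded on round trips", {
  rt <- proportionalResize(4000, 3000, 640)
  out <- rescaleBox(wslBoxes(16, 80, 100, 200), rt, "inverse")
  expect_equal(unlist(out[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 100, ymin = 500, xmax = 625, ymax = 1250))

  ident <- proportionalResize(640, 640, 640)
  b <- wslBoxes(12, 30, 40, 55)
  expect_equal(rescaleBox(b, ident, "forward"), b)

  # round trip starting in the coarser frame reproduces within 1 px
  set.seed(9)
  for (rep in 1:40) {
    down <- proportionalResize(sample(1000:5000, 1), sample(1000:5000, 1), 640)
    co <- c("xmin", "ymin", "xmax", "ymax")
    small <- randomBoxes(1, W = down@targetSize[1], H = down@targetSize[2],
                         conf = FALSE)
    back <- rescaleBox(rescaleBox(small, down, "inverse"), down, "forward")
    expect_lte(max(abs(unlist(back[co]) - unlist(small[co]))), 1)
    up <- proportionalResize(sample(100:600, 1), sample(100:600, 1), 640)
    src <- randomBoxes(1, W = up@sourceSize[1], H = up@sourceSize[2],
                       conf = FALSE)
    back2 <- rescaleBox(rescaleBox(src, up, "forward"), up, "inverse")
    expect_lte(max(abs(unlist(back2[co]) - unlist(src[co]))), 1)
  }
})

test_that("union crop is the clipped margin-expanded bounding rectangle", {
  teeth <- wslBoxes(c(100, 1250), c(500, 625), c(625, 1875), c(1250, 1500))
  u <- unionCrop(teeth, 4000, 3000, margin = 0)
  expect_equal(unlist(u), c(xmin = 100, ymin = 500, xmax = 1875, ymax = 1500))

  one <- teeth[1, , drop = FALSE]
  expect_equal(unionCrop(one, 4000, 3000, 0), one, ignore_attr = TRUE)

  touching <- wslBoxes(0, 0, 100, 100)
  clipped <- unionCrop(touching, 4000, 3000, margin = 50)
  expect_equal(unlist(clipped), c(xmin = 0, ymin = 0, xmax = 150, ymax = 150))

  expect_error(unionCrop(teeth[0, ], 4000, 3000), "at least one")
})

test_that("tile grids follow the stride-then-clamp construction", {
  g1 <- tileGrid(640, 640, 640, 50)
  expect_equal(nrow(tileOffsets(g1)), 1L)
  expect_equal(unname(tileOffsets(g1)[1, ]), c(0L, 0L))

  g2 <- tileGrid(1230, 640, 640, 50)
  expect_equal(sort(unique(tileOffsets(g2)[, "x"])), c(0L, 590L))
  expect_equal(unique(tileOffsets(g2)[, "y"]), 0L)
  # seam overlap exactly 50 px: tile 1 ends at 640, tile 2 starts at 590
  expect_equal(640L - 590L, g2@overlap)

  g3 <- tileGrid(1300, 700, 640, 50)
  expect_equal(sort(unique(tileOffsets(g3)[, "x"])), c(0L, 590L, 660L))
  expect_equal(sort(unique(tileOffsets(g3)[, "y"])), c(0L, 60L))
  expect_equal(nrow(tileOffsets(g3)), 6L)

  expect_error(tileGrid(1000, 1000, 640, 640), "overlap")
})

test_that("tile grids cover every crop pixel with the required overlap", {
  set.seed(21)
  for (rep in 1:60) {
    cw <- sample(100:5000, 1); ch <- sample(100:5000, 1)
    g <- tileGrid(cw, ch, 640, 50)
    for (ax in c("x", "y")) {
      dim <- if (ax == "x") cw else ch
      tileLen <- if (ax == "x") g@tileSize[1] else g@tileSize[2]
      off <- sort(unique(tileOffsets(g)[, ax]))
      expect_true(all(diff(off) > 0))           # strictly increasing
      expect_equal(off[1], 0L)
      expect_equal(off[length(off)] + tileLen, as.integer(dim))  # reaches edge
      if (length(off) > 1) {
        # gapless with >= overlap px shared between neighbours
        expect_true(all(off[-1] + g@overlap <= off[-length(off)] + tileLen))
      }
    }
    # an object no larger than the overlap fits wholly in some tile at any
    # position (consecutive containment windows are gapless iff side <=
    # overlap, which is the coverage the shared border actually guarantees)
    side <- g@overlap
    if (cw > side && ch > side) {
      x0 <- sample.int(cw - side, 1) - 1; y0 <- sample.int(ch - side, 1) - 1
      off <- tileOffsets(g)
      contained <- any(off[, "x"] <= x0 & x0 + side <= off[, "x"] + g@tileSize[1] &
                       off[, "y"] <= y0 & y0 + side <= off[, "y"] + g@tileSize[2])
      expect_true(contained)
    }
  }

  # literal boolean-mask coverage check on scaled-down instances
  set.seed(22)
  for (rep in 1:20) {
    cw <- sample(30:500, 1); ch <- sample(30:500, 1)
    g <- tileGrid(cw, ch, 64, 5)
    mask <- matrix(FALSE, cw, ch)
    off <- tileOffsets(g)
    for (i in seq_len(nrow(off)))
      mask[(off[i, 1] + 1):min(cw, off[i, 1] + g@tileSize[1]),
           (off[i, 2] + 1):min(ch, off[i, 2] + g@tileSize[2])] <- TRUE
    expect_true(all(mask))
  }
})

test_that("tile-to-original remapping is an exact translation round trip", {
  b <- wslBoxes(10, 10, 20, 20)
  out <- toOriginal(b, c(590, 0), c(100, 500))
  expect_equal(unlist(out), c(xmin = 700, ymin = 510, xmax = 710, ymax = 520))
  expect_equal(toOriginal(b, c(0, 0), c(0, 0)), b)
  # round trip original -> tile -> original
  back <- toOriginal(toOriginal(b, c(590, 60), c(100, 500)),
                     c(-590, -60), c(-100, -500))
  expect_equal(back, b)
})
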