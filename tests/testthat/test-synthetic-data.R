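test_that("generation is deterministic: same seed, byte-identical labels", {
  cfg <- generatorConfig(imageWidth = 800, imageHeight = 600, seed = 42)
  d1 <- file.path(tempdir(), "gen-a"); d2 <- file.path(tempdir(), "gen-b")
  generateDataset(cfg, 3, dir = d1, writeImages = FALSE)
  generateDataset(cfg, 3, dir = d2, writeImages = FALSE)
  for (f in list.files(d1, pattern = "\\.txt$")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))

  # rendered pixels are deterministic too
  imgs <- list()
  for (r in 1:2)
    generateDataset(generatorConfig(imageWidth = 480, imageHeight = 360,
                                    seed = 11), 1,
                    callback = function(img, rec)
                      imgs[[r]] <<- img)
  expect_identical(imgs[[1]], imgs[[2]])
})

test_that("peripheral probability one pins every lesion center to the outer band", {
  cfg <- generatorConfig(imageWidth = 1600, imageHeight = 1200,
                         peripheralProb = 1, seed = 12)
  out <- generateDataset(cfg, 10, renderImages = FALSE)
  for (rec in out$records) {
    ann <- annotations(rec)
    teeth <- ann[ann$label == "tooth", , drop = FALSE]
    les <- ann[ann$label == "wsl", , drop = FALSE]
    for (j in seq_len(nrow(les))) {
      inside <- which(teeth$xmin <= les$xmin[j] & teeth$xmax >= les$xmax[j] &
                      teeth$ymin <= les$ymin[j] & teeth$ymax >= les$ymax[j])
      expect_gte(length(inside), 1L)
      t <- teeth[inside[1], ]
      u <- ((les$xmin[j] + les$xmax[j]) / 2 - t$xmin) / (t$xmax - t$xmin)
      v <- ((les$ymin[j] + les$ymax[j]) / 2 - t$ymin) / (t$ymax - t$ymin)
      expect_true(u < 0.25 || u > 0.75 || v < 0.25 || v > 0.75)
    }
  }
})

test_that("invalid generator requests fail fast", {
  expect_error(generateDataset(generatorConfig(), 0), "nImages")
  expect_error(generatorConfig(peripheralProb = 1.4))
  expect_error(generatorConfig(imageWidth = 10))
})

test_that("the self check passes clean output and names corrupted records", {
  cfg <- generatorConfig(imageWidth = 800, imageHeight = 600, seed = 5)
  out <- generateDataset(cfg, 4, renderImages = FALSE)
  sc <- datasetSelfCheck(out$records, cfg)
  expect_true(sc$ok)
  expect_equal(sc$problems, character())

  bad <- out$records
  ann <- annotations(bad[[2]])
  ann$xmax[1] <- 900  # push a box out of the frame
  bad[[2]]@annotations <- ann  # bypass the constructor's validity check
  sc2 <- datasetSelfCheck(bad, cfg)
  expect_false(sc2$ok)
  expect_match(sc2$problems, "synthetic_0002", all = FALSE)
})

test_that("lesion areas track the configured log-normal median", {
  cfg <- generatorConfig(imageWidth = 1600, imageHeight = 1200, seed = 23)
  out <- generateDataset(cfg, 20, renderImages = FALSE)  # ~260 lesions
  sc <- datasetSelfCheck(out$records, cfg)
  expect_gte(sc$nLesions, 200L)
  expect_lt(abs(sc$medianArea - cfg$medianLesionArea),
            0.2 * cfg$medianLesionArea)
})

test_that("downscaling the generated boxes inflates the small-size class", {
  cfg <- generatorConfig(imageWidth = 4000, imageHeight = 3000, seed = 29)
  out <- generateDataset(cfg, 6, renderImages = FALSE)
  lesions <- do.call(rbind, lapply(out$records, function(r) {
    a <- annotations(r); a[a$label == "wsl", , drop = FALSE]
  }))
  rt <- proportionalResize(4000, 3000, 640)
  sh <- downscaleShift(lesions, rt)
  fracBefore <- sh$before@counts[["small"]] / sh$before@n
  fracAfter <- sh$after@counts[["small"]] / sh$after@n
  expect_gt(fracAfter, fracBefore)
})
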