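test_that("scene rendering honours size, labels and the empty-scene case", {
  sc <- renderScene(sceneConfig(), seed = 3)
  expect_identical(dim(scenePixels(sc)), c(128L, 128L, 3L))
  expect_true(is.integer(scenePixels(sc)))
  expect_true(all(scenePixels(sc) >= 0 & scenePixels(sc) <= 255))

  empty <- renderScene(sceneConfig(imageSize = 32, countRange = c(0, 0)),
                       seed = 1)
  expect_identical(fruitCount(empty), 0L)
  expect_identical(nrow(sceneFruits(empty)), 0L)
})

test_that("every generated label equals the number of fruit drawn", {
  for (sc in smokeScenes()) {
    expect_identical(fruitCount(sc), nrow(sceneFruits(sc)))
    f <- sceneFruits(sc)
    if (nrow(f)) {
      expect_true(all(f$radius > 0))
      expect_true(all(f$x >= 1 & f$x <= 32 & f$y >= 1 & f$y <= 32))
    }
  }
})

test_that("visible fractions never fall below the configured floor", {
  vis <- unlist(lapply(smokeScenes(), function(s)
    sceneFruits(s)$visibleFraction))
  expect_true(all(vis >= 0.25 - 1e-9))
  expect_true(all(vis <= 1))
})

test_that("the same configuration and seed render byte-identical scenes", {
  cfg <- sceneConfig(imageSize = 48)
  s1 <- renderScene(cfg, seed = 77)
  s2 <- renderScene(cfg, seed = 77)
  expect_identical(scenePixels(s1), scenePixels(s2))
  expect_identical(sceneFruits(s1), sceneFruits(s2))
  s3 <- renderScene(cfg, seed = 78)
  expect_false(identical(scenePixels(s1), scenePixels(s3)))
})

test_that("dataset generation writes a reproducible manifest that round-trips", {
  cfg <- sceneConfig(imageSize = 32)
  d1 <- file.path(tempdir(), "ds_a")
  d2 <- file.path(tempdir(), "ds_b")
  m1 <- generateDataset(cfg, 5, "train", d1, seed = 5)
  m2 <- generateDataset(cfg, 5, "train", d2, seed = 5)
  expect_identical(nrow(manifestEntries(m1)), 5L)
  expect_identical(manifestEntries(m1)$count, manifestEntries(m2)$count)
  # byte-identical images across the two runs
  for (i in c(1, 5))
    expect_identical(
      readBin(manifestEntries(m1)$path[i], "raw", 1e6),
      readBin(manifestEntries(m2)$path[i], "raw", 1e6))

  pairs <- loadDataset(m1)
  expect_length(pairs, 5)
  expect_identical(vapply(pairs, `[[`, 0L, "count"),
                   manifestEntries(m1)$count)
  cr <- cfg@countRange
  expect_true(all(manifestEntries(m1)$count >= cr[1] &
                    manifestEntries(m1)$count <= cr[2]))

  # the manifest written to disk reloads equivalently
  m1b <- readManifest(d1, "train")
  expect_identical(manifestEntries(m1b)$count, manifestEntries(m1)$count)
})

test_that("an empty dataset yields an empty manifest and no image files", {
  d <- file.path(tempdir(), "ds_empty")
  m <- generateDataset(sceneConfig(imageSize = 32), 0, "train", d, seed = 1)
  expect_identical(nrow(manifestEntries(m)), 0L)
  expect_length(list.files(d, pattern = "\\.png$"), 0)
  expect_length(loadDataset(m), 0)
})

test_that("loading a manifest with a missing file names the offending path", {
  d <- file.path(tempdir(), "ds_missing")
  m <- generateDataset(sceneConfig(imageSize = 32), 3, "train", d, seed = 8)
  victim <- manifestEntries(m)$path[2]
  unlink(victim)
  expect_error(loadDataset(m), basename(victim), fixed = TRUE)
})

test_that("scene counts are uniform over the configured range", {
  cfg <- sceneConfig(imageSize = 16, countRange = c(1, 8),
                     blobCountRange = c(8, 16), occluderProb = 0)
  counts <- vapply(1:1000, function(i)
    fruitCount(renderScene(cfg, seed = 5000 + i)), 0L)
  tab <- tabulate(counts, nbins = 8)
  p <- stats::chisq.test(tab, p = rep(1 / 8, 8))$p.value
  expect_gt(p, 1e-4)
})

test_that("invalid scene configurations are rejected", {
  expect_error(sceneConfig(imageSize = 8), "imageSize")
  expect_error(sceneConfig(countRange = c(5, 2)), "countRange")
  expect_error(sceneConfig(radiusRange = c(0.2, 0.7)), "radiusRange")
  expect_error(sceneConfig(minVisibleFraction = 0), "minVisibleFraction")
  expect_error(sceneConfig(occluderProb = 1.2), "occluderProb")
})
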