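test_that("the YCbCr transform hits its fixed points", {
  red <- rgbToYCbCr(array(c(255, 0, 0), c(1, 1, 3)))
  expect_equal(as.integer(red), c(76L, 85L, 255L))
  gray <- rgbToYCbCr(array(c(128, 128, 128), c(1, 1, 3)))
  expect_identical(as.integer(gray), c(128L, 128L, 128L))
  black <- rgbToYCbCr(array(c(0, 0, 0), c(1, 1, 3)))
  expect_identical(as.integer(black), c(0L, 128L, 128L))
  expect_error(rgbToYCbCr(matrix(0, 4, 4)), "H x W x 3")
})

test_that("segmentation recovers disjoint red disks and ignores foliage", {
  bl <- areaBaselineConfig()
  # all-green image: no fruit chroma, empty mask
  green <- array(rep(c(40, 120, 40), each = 64 * 64), c(64, 64, 3))
  green <- array(as.integer(green), dim(green))
  expect_identical(sum(segmentFruitMask(green, bl)), 0L)

  di <- diskImage(64, list(c(15, 15), c(45, 20), c(30, 48)),
                  c(6, 8, 5))
  mask <- segmentFruitMask(di$image, bl)
  expect_lt(abs(sum(mask) - sum(di$areas)) / sum(di$areas), 0.15)

  # a single isolated fruit-colored pixel is removed by the opening
  speck <- green
  speck[32, 32, ] <- c(220L, 30L, 30L)
  expect_identical(sum(segmentFruitMask(speck, bl)), 0L)
})

test_that("area counts are definitional on disjoint disks and undercount overlap", {
  noMorph <- areaBaselineConfig(morphologyPlan = list())
  r <- 10
  single <- diskImage(80, list(c(40, 40)), r)
  A <- single$areas[1]
  three <- diskImage(80, list(c(20, 20), c(60, 20), c(40, 60)), c(r, r, r))
  mask3 <- segmentFruitMask(three$image, noMorph)
  expect_equal(areaCount(mask3, A), 3, tolerance = 0.05)
  expect_identical(areaCount(matrix(FALSE, 8, 8), 10), 0)
  expect_error(areaCount(mask3, 0), "positive")

  # two disks overlapping by half a disk: union area 1.5 A, so the count
  # is 1.5 -- the occlusion failure mode of area-based counting
  lens <- function(d) 2 * r^2 * acos(d / (2 * r)) -
    d / 2 * sqrt(4 * r^2 - d^2)
  d <- uniroot(function(d) lens(d) - pi * r^2 / 2, c(1, 2 * r - 1e-6))$root
  two <- diskImage(80, list(c(30, 40), c(30 + d, 40)), c(r, r))
  maskO <- segmentFruitMask(two$image, noMorph)
  # pixel-count oracle on the rasterized union
  expect_equal(areaCount(maskO, A), sum(maskO) / A, tolerance = 1e-12)
  expect_equal(areaCount(maskO, A), 1.5, tolerance = 0.07)
  expect_lt(areaCount(maskO, A), 2)
})

test_that("unit-area calibration matches exhaustive search and the single-disk identity", {
  noMorph <- areaBaselineConfig(morphologyPlan = list())
  # scenes holding one disk of exactly A visible pixels calibrate to A
  single <- diskImage(60, list(c(30, 30)), 9)
  A <- single$areas[1]
  scenes1 <- list(list(image = single$image, count = 1L))
  u1 <- calibrateUnitArea(scenes1, noMorph,
                          grid = seq(0.5 * A, 2 * A, by = 1))
  expect_lt(abs(u1 - A), 1)

  # arbitrary scenes: the result equals a brute-force argmin over the grid
  scenes <- lapply(smokeScenes(8), function(s)
    list(image = scenePixels(s), count = fruitCount(s)))
  bl <- areaBaselineConfig()
  grid <- seq(5, 120, by = 2.5)
  u <- calibrateUnitArea(scenes, bl, grid = grid)
  areas <- vapply(scenes, function(s)
    sum(segmentFruitMask(s$image, bl)), 0)
  counts <- vapply(scenes, function(s) as.numeric(s$count), 0)
  cost <- vapply(grid, function(g) sum(abs(areas / g - counts)), 0)
  expect_identical(u, grid[which.min(cost)])

  expect_error(calibrateUnitArea(list(), bl), "no calibration scenes")
})

test_that("area counting is linear in mask area and inverse in unit area", {
  set.seed(3)
  mask <- matrix(runif(400) < 0.3, 20, 20)
  expect_equal(areaCount(mask, 7), sum(mask) / 7, tolerance = 1e-12)
  expect_equal(areaCount(mask, 14), areaCount(mask, 7) / 2,
               tolerance = 1e-12)
  expect_equal(areaCount(rbind(mask, mask), 7), 2 * areaCount(mask, 7),
               tolerance = 1e-12)
})
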