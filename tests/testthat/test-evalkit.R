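test_that("the per-image accuracy formula satisfies its identities", {
  # worked value from a printed prediction/ground-truth pair
  expect_equal(round(accuracyEq1(36, 38), 2), 94.74)
  expect_identical(accuracyEq1(17, 17), 100)
  expect_identical(accuracyEq1(0, 10), 0)
  # symmetric in over/under-counting, unclamped below zero
  expect_equal(accuracyEq1(25, 20), accuracyEq1(15, 20))
  expect_lt(accuracyEq1(45, 20), 0)
  expect_true(all(accuracyEq1(c(10, 30), c(20, 20)) < 100))
  expect_error(accuracyEq1(5, 0), "undefined")
})

test_that("linear fits match the normal-equations oracle", {
  perfect <- linearFit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect@slope, 1, tolerance = 1e-12)
  expect_equal(perfect@intercept, 0, tolerance = 1e-12)
  expect_equal(perfect@rSquared, 1, tolerance = 1e-12)

  # hand-solved least squares for (1,2), (2,2), (3,4)
  fit <- linearFit(c(2, 2, 4), c(1, 2, 3))
  expect_equal(fit@slope, 1, tolerance = 1e-12)
  expect_equal(fit@intercept, 2 / 3, tolerance = 1e-12)
  expect_equal(fit@rSquared, 0.75, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(12, 20, 6); y <- 0.9 * x + rnorm(12)
    o <- olsOracle(x, y)
    f <- linearFit(y, x)
    expect_equal(f@slope, o$slope, tolerance = 1e-9)
    expect_equal(f@intercept, o$intercept, tolerance = 1e-9)
    expect_equal(f@rSquared, o$r2, tolerance = 1e-9)
  }
  expect_error(linearFit(1, 1), "two points")
  expect_error(linearFit(c(1, 2), c(3, 3)), "degenerate")
})

test_that("evaluation reports aggregate per-image records correctly", {
  imgs <- lapply(1:10, function(i) array(0L, c(8, 8, 3)))
  ac <- c(12, 25, 38, 7, 19, 30, 3, 40, 14, 22)
  data <- lapply(1:10, function(i) list(image = imgs[[i]], count = ac[i]))

  # perfect predictor: accuracy 100, MSE 0, R^2 1
  rep0 <- evaluatePredictor(function(images) ac, data,
                            methodName = "oracle")
  expect_identical(meanAccuracy(rep0), 100)
  expect_identical(countMSE(rep0), 0)
  expect_equal(regressionFit(rep0)@rSquared, 1, tolerance = 1e-12)

  # constant offset: RMSE equals the offset
  rep1 <- evaluatePredictor(function(images) ac + 2, data,
                            rounding = FALSE)
  expect_equal(countRMSE(rep1), 2, tolerance = 1e-12)

  # fixed noisy predictor against a step-by-step accumulation oracle
  set.seed(17)
  noise <- rnorm(10, 0, 3)
  pc <- ac + noise
  rep2 <- evaluatePredictor(function(images) pc, data, rounding = FALSE)
  paOracle <- mseOracle <- 0
  for (i in 1:10) {
    paOracle <- paOracle + (1 - abs(pc[i] - ac[i]) / ac[i]) * 100
    mseOracle <- mseOracle + (pc[i] - ac[i])^2
  }
  expect_equal(meanAccuracy(rep2), paOracle / 10, tolerance = 1e-9)
  expect_equal(countMSE(rep2), mseOracle / 10, tolerance = 1e-9)
  expect_equal(countRMSE(rep2)^2, countMSE(rep2), tolerance = 1e-9)
  # record order does not change the mean accuracy
  rep2b <- evaluatePredictor(function(images) rev(pc), rev(data),
                             rounding = FALSE)
  expect_equal(meanAccuracy(rep2b), meanAccuracy(rep2), tolerance = 1e-9)

  # rounded and raw conventions differ only in the accuracy column
  rep3 <- evaluatePredictor(function(images) pc, data, rounding = TRUE)
  expect_identical(countMSE(rep3), countMSE(rep2))
  expect_equal(reportRecords(rep3)$pa,
               accuracyEq1(floor(pc + 0.5), ac), tolerance = 1e-12)

  # a zero actual count is rejected with advice
  bad <- data
  bad[[4]]$count <- 0
  expect_error(evaluatePredictor(function(images) pc, bad), "regenerate")
})

test_that("method comparison tables rank by accuracy", {
  imgs <- lapply(1:6, function(i) array(0L, c(8, 8, 3)))
  ac <- c(10, 20, 30, 15, 25, 35)
  data <- lapply(1:6, function(i) list(image = imgs[[i]], count = ac[i]))
  good <- evaluatePredictor(function(x) ac + 1, data, methodName = "good")
  bad <- evaluatePredictor(function(x) ac * 0.5, data, methodName = "bad")
  tab <- compareMethods(list(bad, good))
  expect_identical(tab$method, c("good", "bad"))
  expect_equal(tab$meanAccuracy[1], meanAccuracy(good), tolerance = 1e-12)
  expect_equal(tab$rmse[2], countRMSE(bad), tolerance = 1e-12)
  one <- compareMethods(list(good))
  expect_identical(nrow(one), 1L)
  expect_error(compareMethods(list()), "at least one")
})

test_that("reports serialize to CSV and JSON", {
  imgs <- lapply(1:4, function(i) array(0L, c(8, 8, 3)))
  data <- lapply(1:4, function(i) list(image = imgs[[i]],
                                       count = c(5, 9, 13, 21)[i]))
  rep <- evaluatePredictor(function(x) c(5, 10, 12, 20), data,
                           methodName = "m")
  csv <- tempfile(fileext = ".csv")
  reportToCSV(rep, csv)
  back <- read.csv(csv)
  expect_equal(back$ac, c(5, 9, 13, 21))
  js <- tempfile(fileext = ".json")
  reportToJSON(rep, js)
  obj <- jsonlite::read_json(js)
  expect_equal(obj$meanAccuracy, meanAccuracy(rep), tolerance = 1e-9)
  expect_length(obj$records, 4)
})
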