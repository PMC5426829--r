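test_that("Xavier initialization has the Glorot variance and fixed state values", {
  gcns <- asNamespace("glanceCount")
  spec <- networkSpec(list(
    list(name = "input", kind = "input"),
    gcns$nodeConv("c", "input", 3, 8),
    gcns$nodeBN("b", "c"),
    gcns$nodeFlatten("fl", "b"),
    gcns$nodeFC("big", "fl", 1000)), 19)
  params <- xavierInit(spec, seed = 4)
  # large fc layer: empirical variance within 10% of 2 / (fanIn + fanOut)
  W <- params[["big.W"]]
  fanIn <- ncol(W); fanOut <- nrow(W)
  expect_lt(abs(var(as.numeric(W)) / (2 / (fanIn + fanOut)) - 1), 0.1)
  # conv kernels follow the same rule with kernel-area fan terms
  Wc <- params[["c.W"]]
  expect_lt(abs(var(as.numeric(Wc)) / (2 / (9 * 3 + 9 * 8)) - 1), 0.15)
  # batchnorm shift exactly 0, scale exactly 1, biases exactly 0
  expect_true(all(params[["b.beta"]] == 0))
  expect_true(all(params[["b.gamma"]] == 1))
  expect_true(all(params[["big.b"]] == 0))
  # deterministic per seed
  expect_identical(params, xavierInit(spec, seed = 4))
  expect_false(identical(params[["big.W"]],
                         xavierInit(spec, seed = 5)[["big.W"]]))
})

test_that("the MSE cost matches an elementwise accumulation oracle", {
  expect_identical(mseLoss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(mseLoss(3, 5), 4)
  set.seed(8)
  p <- rnorm(10, 20, 5); y <- round(runif(10, 1, 40))
  acc <- 0
  for (i in 1:10) acc <- acc + (p[i] - y[i])^2
  expect_equal(mseLoss(p, y), acc / 10, tolerance = 1e-12)
  expect_error(mseLoss(numeric(), numeric()), "at least one")
  expect_error(mseLoss(1:3, 1:2), "equal length")
})

test_that("EMA updates obey the limit cases and the scalar recurrence", {
  a <- list(w = matrix(1:4, 2), b = matrix(0.5))
  b <- list(w = matrix(5:8, 2), b = matrix(-1))
  expect_equal(emaUpdate(a, b, 0), b)
  expect_equal(emaUpdate(a, b, 1), a)
  # 5-step sequence against a hand-rolled scalar recurrence
  decay <- 0.8
  ema <- list(w = matrix(0))
  scalar <- 0
  targets <- c(1, 2, -3, 4, 0.5)
  for (t in targets) {
    ema <- emaUpdate(ema, list(w = matrix(t)), decay)
    scalar <- decay * scalar + (1 - decay) * t
    expect_equal(ema$w[1, 1], scalar, tolerance = 1e-12)
  }
  # with parameters held fixed the EMA converges geometrically to them
  ema <- list(w = matrix(10))
  for (i in 1:60) ema <- emaUpdate(ema, list(w = matrix(2)), 0.8)
  expect_equal(ema$w[1, 1], 2 + 8 * 0.8^60, tolerance = 1e-12)
  expect_error(emaUpdate(a, list(w = matrix(1:6, 3), b = matrix(1)), 0.5),
               "shape mismatch")
})

test_that("analytic gradients match central finite differences", {
  gcns <- asNamespace("glanceCount")
  # one instance of every node kind, dropout disabled for differentiability
  nodes <- list(
    list(name = "input", kind = "input"),
    gcns$nodeConv("c1", "input", 3, 4, stride = 2, padding = "SAME"),
    gcns$nodeBN("b1", "c1"), gcns$nodeReLU("r1", "b1"),
    gcns$nodeConv("c2a", "r1", 1, 2), gcns$nodeBN("b2a", "c2a"),
    gcns$nodeReLU("r2a", "b2a"),
    gcns$nodeConv("c2b", "r1", 3, 2), gcns$nodeBN("b2b", "c2b"),
    gcns$nodeReLU("r2b", "b2b"),
    gcns$nodeConcat("cc", c("r2a", "r2b")),
    gcns$nodeConv("proj", "cc", 1, 4), gcns$nodeBN("bp", "proj"),
    gcns$nodeAdd("add", "r1", "bp", scale = 0.7),
    gcns$nodeReLU("ra", "add"),
    gcns$nodePool("mp", "ra", "maxpool", 2, 2),
    gcns$nodePool("ap", "mp", "avgpool", 2, 2),
    gcns$nodeFlatten("fl", "ap"),
    gcns$nodeFC("fc1", "fl", 5), gcns$nodeReLU("rf", "fc1"),
    gcns$nodeFC("out", "rf", 1))
  spec <- networkSpec(nodes, 12)
  plan <- gcns$compilePlan(spec)
  set.seed(21)
  X <- matrix(runif(12 * 12 * 3 * 3), ncol = 3)
  y <- c(4, 9, 15)
  params <- xavierInit(spec, seed = 6)
  # keep activations away from the rectifier kink so finite differences
  # are informative
  for (k in names(params)) {
    if (grepl("\\.beta$", k)) params[[k]][] <- 0.3
    if (grepl("\\.gamma$", k))
      params[[k]][] <- 1 + runif(length(params[[k]]), -0.2, 0.2)
  }
  lossAt <- function(p)
    mean((gcns$runForward(plan, p, X, training = TRUE)$pred - y)^2)
  fw <- gcns$runForward(plan, params, X, training = TRUE, keepCache = TRUE)
  grads <- gcns$runBackward(plan, params, fw, 2 * (fw$pred - y) / 3)
  tkeys <- names(params)[gcns$isTrainableKey(names(params))]
  set.seed(2)
  for (rep in 1:30) {
    k <- sample(tkeys, 1)
    i <- sample(length(params[[k]]), 1)
    eps <- 1e-6
    p1 <- params; p1[[k]][i] <- p1[[k]][i] + eps
    p2 <- params; p2[[k]][i] <- p2[[k]][i] - eps
    fd <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
    an <- grads[[k]][i]
    expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4,
              label = sprintf("gradient of %s[%d]", k, i))
  }
})

test_that("a zero learning rate leaves the weights untouched and the loss flat", {
  run <- smokeRun()
  spec <- buildCountNet(0.25, 32)
  # full-batch, no dropout: every step sees the same data and weights
  cfg <- trainConfig(epochs = 2, learningRate = 0, batchSize = 200,
                     dropoutKeep = 1, seed = 9)
  model <- trainNetwork(spec, run$trainMan, config = cfg)
  init <- xavierInit(spec, seed = 9)
  tkeys <- names(init)[grepl("\\.(W|b|gamma|beta)$", names(init))]
  for (k in tkeys) expect_identical(modelParameters(model)[[k]], init[[k]])
  h <- trainingHistory(model)
  expect_length(h, 2)
  expect_equal(h[1], h[2], tolerance = 1e-12)
})

test_that("training is reproducible from the seed and records every step", {
  run <- smokeRun()
  spec <- buildCountNet(0.25, 32)
  cfg <- trainConfig(epochs = 1, batchSize = 64, seed = 13)
  m1 <- trainNetwork(spec, run$trainMan, config = cfg)
  m2 <- trainNetwork(spec, run$trainMan, config = cfg)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_length(trainingHistory(m1), ceiling(200 / 64))
  expect_identical(modelParameters(m1)[["head_out.W"]],
                   modelParameters(m2)[["head_out.W"]])
  expect_identical(emaParameters(m1)[["head_out.W"]],
                   emaParameters(m2)[["head_out.W"]])
})

test_that("a short smoke training beats the constant mean predictor", {
  run <- smokeRun()
  valMSE <- attr(trainingHistory(run$model), "valMSE")
  labels <- manifestEntries(run$testMan)$count
  meanPredictorMSE <- mean((mean(labels) - labels)^2)
  expect_lt(valMSE, meanPredictorMSE)
  # smoothed training loss decreases from the first epoch to the last
  h <- trainingHistory(run$model)
  nb <- length(h) / 3
  expect_lt(mean(tail(h, nb)), mean(head(h, nb)))
})

test_that("model checkpoints round-trip through disk", {
  run <- smokeRun()
  d <- file.path(tempdir(), "ckpt_fixture")
  saveCheckpoint(run$model, d)
  back <- loadCheckpoint(d)
  expect_equal(trainingHistory(back),
               as.numeric(trainingHistory(run$model)),
               tolerance = 1e-12)
  pairs <- loadDataset(run$testMan)[1:5]
  expect_equal(predictCounts(back, lapply(pairs, `[[`, "image")),
               predictCounts(run$model, lapply(pairs, `[[`, "image")),
               tolerance = 1e-12)
})
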