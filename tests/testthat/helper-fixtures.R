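# Shared fixtures.  Expensive artifacts (rendered scene sets, trained
# models) are built once per session and cached here for reuse across test
# files.

fixtureEnv <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(fixtureEnv[[key]])) fixtureEnv[[key]] <- builder()
  fixtureEnv[[key]]
}

# A small set of rendered 32 px scenes under the default occlusion/shadow
# regime.
smokeScenes <- function(n = 20, seed0 = 100) {
  cached(sprintf("scenes_%d_%d", n, seed0), function() {
    cfg <- sceneConfig(imageSize = 32)
    lapply(seq_len(n), function(i) renderScene(cfg, seed = seed0 + i))
  })
}

# Smoke-scale training run: 200 images at 32 px, width 0.25, 3 epochs.
smokeRun <- function() {
  cached("smokeRun", function() {
    dir <- file.path(tempdir(), "smoke_fixture")
    cfg <- sceneConfig(imageSize = 32)
    trainMan <- generateDataset(cfg, 200, "train", dir, seed = 41)
    testMan <- generateDataset(cfg, 50, "test", dir, seed = 42)
    spec <- buildCountNet(widthMultiplier = 0.25, inputSize = 32)
    model <- trainNetwork(spec, trainMan, valData = testMan,
                          config = trainConfig(seed = 7))
    list(trainMan = trainMan, testMan = testMan, model = model)
  })
}

# Flat-color image with red disks painted on a green background; returns
# the image plus the rasterized pixel area of each disk.
diskImage <- function(H, centers, radii, bg = c(40, 110, 40),
                      fg = c(220, 30, 30)) {
  img <- array(rep(bg, each = H * H), c(H, H, 3))
  areas <- numeric(length(radii))
  for (i in seq_along(radii)) {
    g <- expand.grid(y = 1:H, x = 1:H)
    inside <- (g$x - centers[[i]][1])^2 + (g$y - centers[[i]][2])^2 <=
      radii[i]^2
    areas[i] <- sum(inside)
    for (ch in 1:3)
      img[cbind(g$y[inside], g$x[inside], ch)] <- fg[ch]
  }
  list(image = array(as.integer(img), dim(img)), areas = areas)
}

# Independent normal-equations solution for simple linear regression.
olsOracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  pred <- intercept + slope * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}
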