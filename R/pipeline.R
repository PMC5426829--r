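# End-to-end wiring: generate -> train -> evaluate -> baseline -> compare,
# reproducible from a single configuration and master seed.

# Reduced-scale profiles use a smaller minibatch so the optimizer step
# budget stays comparable to the full-scale run (24000 x 3 / 64 = 1125
# steps) despite the smaller dataset; see the methods vignette.
profileDefaults <- function(profile) {
  switch(profile,
    smoke = list(imageSize = 32L, nTrain = 200L, nTest = 50L,
                 widthMultiplier = 0.25, nCalibration = 30L,
                 batchSize = 16L),
    desk = list(imageSize = 64L, nTrain = 4000L, nTest = 400L,
                widthMultiplier = 0.5, nCalibration = 100L,
                batchSize = 16L),
    full = list(imageSize = 128L, nTrain = 24000L, nTest = 2400L,
                 widthMultiplier = 1, nCalibration = 200L,
                 batchSize = 64L),
    stop(sprintf("unknown profile '%s'", profile)))
}

#' Construct a pipeline run configuration
#'
#' Three bundled profiles set the dataset and network scale:
#' \describe{
#'   \item{`smoke`}{200/50 images at 32 px, width 0.25 -- a desk test that
#'     completes in minutes.}
#'   \item{`desk`}{4000/400 images at 64 px, width 0.5 -- the scaled-down
#'     evaluation setting.}
#'   \item{`full`}{24000/2400 images at 128 px, width 1 -- the full-scale
#'     study configuration (long runtime on CPU).}
#' }
#' Individual fields can be overridden after construction through the
#' arguments.
#'
#' @param profile one of `"smoke"`, `"desk"`, `"full"`.
#' @param seed master seed; all stage seeds are derived from it.
#' @param outDir output directory for datasets, checkpoints and reports.
#' @param nTrain,nTest,widthMultiplier,imageSize,nCalibration optional
#'   overrides of the profile values.
#' @param scene optional [SceneConfig-class] replacing the profile scene
#'   (its imageSize must match).
#' @param train optional [TrainConfig-class].
#' @param baseline optional [AreaBaselineConfig-class].
#' @return a [RunConfig-class].
#' @export
runConfig <- function(profile = "smoke", seed = 1,
                      outDir = file.path(tempdir(), paste0("run_", profile)),
                      nTrain = NULL, nTest = NULL, widthMultiplier = NULL,
                      imageSize = NULL, nCalibration = NULL, scene = NULL,
                      train = NULL, baseline = NULL) {
  pd <- profileDefaults(profile)
  nTrain <- as.integer(nTrain %||% pd$nTrain)
  nTest <- as.integer(nTest %||% pd$nTest)
  widthMultiplier <- widthMultiplier %||% pd$widthMultiplier
  imageSize <- as.integer(imageSize %||% pd$imageSize)
  nCalibration <- as.integer(min(nCalibration %||% pd$nCalibration, nTrain))
  scene <- scene %||% sceneConfig(imageSize = imageSize, seed = seed)
  if (scene@imageSize != imageSize)
    scene@imageSize <- imageSize
  train <- train %||% trainConfig(seed = deriveSeed(seed, 101L),
                                  batchSize = pd$batchSize)
  baseline <- baseline %||% areaBaselineConfig()
  obj <- new("RunConfig", scene = scene, train = train,
             widthMultiplier = widthMultiplier, nTrain = nTrain,
             nTest = nTest, baseline = baseline,
             nCalibration = nCalibration, outDir = outDir,
             seed = as.integer(seed), profile = profile)
  validObject(obj)
  obj
}

runConfigToList <- function(config) {
  list(profile = config@profile, seed = config@seed,
       nTrain = config@nTrain, nTest = config@nTest,
       widthMultiplier = config@widthMultiplier,
       imageSize = config@scene@imageSize,
       nCalibration = config@nCalibration,
       scene = sceneConfigToList(config@scene),
       train = list(epochs = config@train@epochs,
                    learningRate = config@train@learningRate,
                    batchSize = config@train@batchSize,
                    dropoutKeep = config@train@dropoutKeep,
                    emaDecay = config@train@emaDecay,
                    seed = config@train@seed),
       baseline = list(crMin = config@baseline@crMin,
                       cbMax = config@baseline@cbMax))
}

#' Load a pipeline configuration from YAML
#'
#' An empty file yields the default smoke profile.  Unknown keys are
#' rejected with the offending key path; sub-configuration values are
#' validated on construction.
#'
#' @param path YAML file.
#' @return a [RunConfig-class].
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("no config file at '%s'", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  topKeys <- c("profile", "seed", "outDir", "nTrain", "nTest",
               "widthMultiplier", "imageSize", "nCalibration", "scene",
               "train", "baseline")
  bad <- setdiff(names(raw), topKeys)
  if (length(bad)) stop(sprintf("unknown configuration key: '%s'", bad[1]))
  sceneKeys <- c("imageSize", "countRange", "radiusRange", "ripenessMix",
                 "blobCountRange", "paletteJitter", "blurSigma",
                 "fullBlurSigma", "illumAmplitude", "shadowProb",
                 "occluderProb", "minVisibleFraction", "seed")
  trainKeys <- c("epochs", "learningRate", "batchSize", "dropoutKeep",
                 "emaDecay", "seed")
  blKeys <- c("crMin", "cbMax")
  for (sub in c("scene", "train", "baseline")) {
    keys <- switch(sub, scene = sceneKeys, train = trainKeys,
                   baseline = blKeys)
    bad <- setdiff(names(raw[[sub]]), keys)
    if (length(bad))
      stop(sprintf("unknown configuration key: '%s.%s'", sub, bad[1]))
  }
  profile <- raw$profile %||% "smoke"
  seed <- as.integer(raw$seed %||% 1L)
  imageSize <- raw$imageSize %||% profileDefaults(profile)$imageSize
  scene <- NULL
  if (!is.null(raw$scene)) {
    sargs <- raw$scene
    sargs$imageSize <- sargs$imageSize %||% imageSize
    if (!is.null(sargs$countRange)) sargs$countRange <- unlist(sargs$countRange)
    if (!is.null(sargs$radiusRange))
      sargs$radiusRange <- unlist(sargs$radiusRange)
    if (!is.null(sargs$blobCountRange))
      sargs$blobCountRange <- unlist(sargs$blobCountRange)
    scene <- do.call(sceneConfig, sargs)
  }
  train <- NULL
  if (!is.null(raw$train)) {
    targs <- raw$train
    targs$seed <- targs$seed %||% deriveSeed(seed, 101L)
    train <- do.call(trainConfig, targs)
  }
  baseline <- if (!is.null(raw$baseline))
    do.call(areaBaselineConfig, raw$baseline) else NULL
  args <- list(profile = profile, seed = seed, scene = scene,
               train = train, baseline = baseline)
  for (k in c("outDir", "nTrain", "nTest", "widthMultiplier", "imageSize",
              "nCalibration"))
    args[[k]] <- raw[[k]]
  do.call(runConfig, args[!vapply(args, is.null, TRUE)])
}

#' Write a pipeline configuration to YAML
#'
#' @param config a [RunConfig-class].
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
dumpRunConfig <- function(config, path) {
  x <- runConfigToList(config)
  x$scene$palette <- NULL  # palette matrices stay at their defaults in YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full counting pipeline
#'
#' Generates train and test splits, trains the deep counting network,
#' calibrates and evaluates the area-based baseline and (optionally) the
#' shallow network on the same test split, and writes all artifacts --
#' datasets, a model checkpoint, per-method reports and the comparison
#' table -- under the configuration's output directory together with a JSON
#' snapshot of every seed used.  Reruns with the same configuration
#' reproduce the same comparison table.
#'
#' @param config a [RunConfig-class].
#' @param methods subset of `c("deep", "area", "shallow")` to evaluate.
#' @param verbose print stage progress.
#' @return list with elements `reports` (named list of
#'   [EvalReport-class]), `comparison` (data.frame), `deepModel`,
#'   `shallowModel` (when run), `unitArea`, and the manifests.
#' @export
runPipeline <- function(config, methods = c("deep", "area", "shallow"),
                        verbose = FALSE) {
  validObject(config)
  methods <- match.arg(methods, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  dataDir <- file.path(config@outDir, "data")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("generating %d training and %d test scenes (%d px)",
      config@nTrain, config@nTest, config@scene@imageSize)
  trainMan <- stage("generate", generateDataset(
    config@scene, config@nTrain, "train", dataDir,
    seed = deriveSeed(config@seed, 1L)))
  testMan <- stage("generate", generateDataset(
    config@scene, config@nTest, "test", dataDir,
    seed = deriveSeed(config@seed, 2L)))

  testData <- stage("load", loadDataset(testMan))
  inputSize <- config@scene@imageSize
  testPre <- list(X = imagesToMatrix(lapply(testData, `[[`, "image"),
                                     inputSize),
                  y = vapply(testData, `[[`, 0, "count"))

  reports <- list()
  out <- list(trainManifest = trainMan, testManifest = testMan)

  if ("deep" %in% methods) {
    say("training the deep counting network (width x%.2f)",
        config@widthMultiplier)
    spec <- buildCountNet(config@widthMultiplier, inputSize,
                          dropoutKeep = config@train@dropoutKeep)
    model <- stage("train", trainNetwork(spec, trainMan, valData = NULL,
                                         config = config@train,
                                         verbose = verbose))
    out$deepModel <- model
    stage("checkpoint", saveCheckpoint(model,
                                       file.path(config@outDir, "deep_ckpt")))
    predDeep <- function(images) predictCounts(model, testPre)
    reports$deep <- stage("evaluate", evaluatePredictor(
      predDeep, testData, rounding = TRUE, methodName = "deep"))
  }

  if ("area" %in% methods) {
    say("calibrating the area-based baseline on %d scenes",
        config@nCalibration)
    calData <- stage("load", loadDataset(new(
      "DatasetManifest", splitName = "calibration",
      entries = head(manifestEntries(trainMan), config@nCalibration),
      config = config@scene, seed = trainMan@seed)))
    unitArea <- stage("calibrate",
                      calibrateUnitArea(calData, config@baseline))
    bl <- config@baseline
    bl@unitArea <- unitArea
    out$unitArea <- unitArea
    reports$area <- stage("evaluate", evaluatePredictor(
      areaPredictor(bl), testData, rounding = TRUE, methodName = "area"))
  }

  if ("shallow" %in% methods) {
    say("training the shallow baseline network")
    sspec <- buildShallowNet(inputSize)
    strain <- config@train
    strain@seed <- deriveSeed(config@seed, 301L)
    smodel <- stage("train", trainNetwork(sspec, trainMan, valData = NULL,
                                          config = strain,
                                          verbose = verbose))
    out$shallowModel <- smodel
    predShallow <- function(images) predictCounts(smodel, testPre)
    reports$shallow <- stage("evaluate", evaluatePredictor(
      predShallow, testData, rounding = TRUE, methodName = "shallow"))
  }

  comparison <- compareMethods(reports)
  out$reports <- reports
  out$comparison <- comparison
  stage("write", {
    write.csv(comparison, file.path(config@outDir, "comparison.csv"),
              row.names = FALSE)
    for (nm in names(reports))
      reportToCSV(reports[[nm]],
                  file.path(config@outDir, paste0("report_", nm, ".csv")))
    jsonlite::write_json(
      c(runConfigToList(config),
        list(stageSeeds = list(trainSplit = deriveSeed(config@seed, 1L),
                               testSplit = deriveSeed(config@seed, 2L),
                               deepTrain = config@train@seed,
                               shallowTrain = deriveSeed(config@seed, 301L)))),
      file.path(config@outDir, "run.json"), auto_unbox = TRUE, digits = NA)
  })
  out
}
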