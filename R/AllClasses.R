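#' Scene-generator configuration
#'
#' Parameters of the synthetic tomato-scene generator.  Scenes are square RGB
#' rasters: a cluttered background of green/brown blobs blurred with a
#' Gaussian filter, shaded circular fruit of variable size drawn with some
#' degree of overlap, optional foliage occluders painted over the fruit
#' layer, and a smooth multiplicative illumination field with per-fruit
#' shadows.
#'
#' @slot imageSize integer, pixels per side (square images).
#' @slot countRange integer length-2, inclusive range of fruit per scene;
#'   counts are drawn uniformly from this range.
#' @slot radiusRange numeric length-2, fruit radius as a fraction of the
#'   image side.
#' @slot ripenessMix numeric, probability that a fruit is ripe (red) rather
#'   than half-ripe (orange).
#' @slot blobCountRange integer length-2, number of background blobs.
#' @slot palette 3-column numeric matrix of background base colors (RGB,
#'   0-255), greens and browns.
#' @slot paletteJitter numeric, per-channel uniform jitter amplitude added to
#'   background base colors.
#' @slot blurSigma numeric, standard deviation (pixels) of the Gaussian blur
#'   applied to the background layer.
#' @slot fullBlurSigma numeric, optional light blur applied to the finished
#'   image to mimic camera softness; 0 disables it (the default).
#' @slot illumAmplitude numeric in [0, 1], amplitude of the multiplicative
#'   low-frequency brightness field.
#' @slot shadowProb numeric, probability that an individual fruit is darkened
#'   as if under shadow.
#' @slot occluderProb numeric, probability that a foliage blob is drawn over
#'   the fruit layer, per fruit.
#' @slot minVisibleFraction numeric in (0, 1], minimum fraction of a fruit's
#'   disk that must remain visible; placements violating it are retried so
#'   count labels stay honest.
#' @slot seed integer, generator seed.
#' @seealso [sceneConfig()], [renderScene()], [generateDataset()]
#' @exportClass SceneConfig
setClass("SceneConfig", representation(
  imageSize = "integer",
  countRange = "integer",
  radiusRange = "numeric",
  ripenessMix = "numeric",
  blobCountRange = "integer",
  palette = "matrix",
  paletteJitter = "numeric",
  blurSigma = "numeric",
  fullBlurSigma = "numeric",
  illumAmplitude = "numeric",
  shadowProb = "numeric",
  occluderProb = "numeric",
  minVisibleFraction = "numeric",
  seed = "integer"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  p01 <- function(x) length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
  if (length(object@imageSize) != 1 || object@imageSize < 16)
    msg <- c(msg, "imageSize must be a single integer >= 16")
  cr <- object@countRange
  if (length(cr) != 2 || any(cr < 0) || cr[1] > cr[2])
    msg <- c(msg, "countRange must be 0 <= low <= high")
  rr <- object@radiusRange
  if (length(rr) != 2 || any(rr <= 0) || any(rr >= 0.5) || rr[1] > rr[2])
    msg <- c(msg, "radiusRange fractions must lie in (0, 0.5) with low <= high")
  if (!p01(object@ripenessMix)) msg <- c(msg, "ripenessMix must be in [0, 1]")
  br <- object@blobCountRange
  if (length(br) != 2 || any(br < 0) || br[1] > br[2])
    msg <- c(msg, "blobCountRange must be 0 <= low <= high")
  if (ncol(object@palette) != 3 || nrow(object@palette) < 1)
    msg <- c(msg, "palette must be an n x 3 RGB matrix")
  if (object@blurSigma < 0) msg <- c(msg, "blurSigma must be >= 0")
  if (object@fullBlurSigma < 0) msg <- c(msg, "fullBlurSigma must be >= 0")
  if (!p01(object@illumAmplitude))
    msg <- c(msg, "illumAmplitude must be in [0, 1]")
  if (!p01(object@shadowProb)) msg <- c(msg, "shadowProb must be in [0, 1]")
  if (!p01(object@occluderProb))
    msg <- c(msg, "occluderProb must be in [0, 1]")
  mv <- object@minVisibleFraction
  if (length(mv) != 1 || !is.finite(mv) || mv <= 0 || mv > 1)
    msg <- c(msg, "minVisibleFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Rendered synthetic scene with its exact count label
#'
#' @slot pixels imageSize x imageSize x 3 integer array of 8-bit RGB values.
#' @slot count integer, the exact number of fruit drawn.
#' @slot fruits data.frame with one row per fruit: columns `x`, `y` (center,
#'   pixels), `radius` (pixels), `ripeness` (`"ripe"` or `"half_ripe"`) and
#'   `visibleFraction`.
#' @slot seed integer, the per-scene RNG seed used.
#' @seealso [renderScene()]
#' @exportClass LabeledScene
setClass("LabeledScene", representation(
  pixels = "array", count = "integer", fruits = "data.frame",
  seed = "integer"
))

setValidity("LabeledScene", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3 || d[3] != 3 || d[1] != d[2])
    msg <- c(msg, "pixels must be a square H x H x 3 array")
  if (object@count != nrow(object@fruits))
    msg <- c(msg, "count must equal the number of fruit records")
  if (nrow(object@fruits) > 0) {
    f <- object@fruits
    if (any(f$radius <= 0)) msg <- c(msg, "fruit radii must be positive")
    if (any(f$x < 1 | f$x > d[2] | f$y < 1 | f$y > d[1]))
      msg <- c(msg, "fruit centers must lie within the image")
    if (any(f$visibleFraction <= 0 | f$visibleFraction > 1))
      msg <- c(msg, "visibleFraction must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Dataset manifest
#'
#' Ordered record of a generated image set: file paths, count labels, the
#' scene configuration snapshot and the master seed, sufficient to reproduce
#' the dataset byte for byte.
#'
#' @slot splitName character, e.g. `"train"` or `"test"`.
#' @slot entries data.frame with columns `path` and `count`, in generation
#'   order.
#' @slot config the [SceneConfig-class] snapshot used.
#' @slot seed integer master seed; per-image seeds are derived from it.
#' @seealso [generateDataset()], [loadDataset()]
#' @exportClass DatasetManifest
setClass("DatasetManifest", representation(
  splitName = "character", entries = "data.frame", config = "SceneConfig",
  seed = "integer"
))

setValidity("DatasetManifest", function(object) {
  msg <- character()
  if (!all(c("path", "count") %in% names(object@entries)))
    msg <- c(msg, "entries must have columns `path` and `count`")
  if (nrow(object@entries) > 0) {
    cr <- object@config@countRange
    if (any(object@entries$count < cr[1] | object@entries$count > cr[2]))
      msg <- c(msg, "all counts must lie within the configured countRange")
  }
  if (length(msg)) msg else TRUE
})

#' Declarative network architecture
#'
#' A counting network is a directed acyclic graph of named primitive nodes
#' (`input`, `conv`, `batchnorm`, `relu`, `maxpool`, `avgpool`, `fc`,
#' `dropout`, `flatten`, `concat`, `add`).  Composite blocks — the modified
#' Inception-ResNet-A module and the modified reduction module — are expanded
#' into these primitives at build time, so structural invariants (a batchnorm
#' after every convolution, shape-compatible residual additions) can be
#' checked by scanning the graph.
#'
#' @slot nodes list of node descriptions; each is a list with fields `name`,
#'   `kind`, `inputs` (names of producer nodes) and kind-specific fields
#'   (`kernel`, `stride`, `padding`, `outChannels`, `keep`, `scale`).
#' @slot inputSize integer, expected image side in pixels.
#' @slot widthMultiplier numeric, channel-width scaling used by the builder
#'   (1 is the reference network).
#' @slot name character label.
#' @seealso [buildCountNet()], [buildShallowNet()], [inferShapes()],
#'   [forwardNetwork()]
#' @exportClass NetworkSpec
setClass("NetworkSpec", representation(
  nodes = "list", inputSize = "integer", widthMultiplier = "numeric",
  name = "character"
))

setValidity("NetworkSpec", function(object) {
  msg <- character()
  kinds <- c("input", "conv", "batchnorm", "relu", "maxpool", "avgpool",
             "fc", "dropout", "flatten", "concat", "add")
  seen <- character()
  for (nd in object@nodes) {
    if (is.null(nd$name) || is.null(nd$kind)) {
      msg <- c(msg, "every node needs `name` and `kind`"); break
    }
    if (!nd$kind %in% kinds)
      msg <- c(msg, sprintf("unknown node kind '%s'", nd$kind))
    if (nd$name %in% seen)
      msg <- c(msg, sprintf("duplicate node name '%s'", nd$name))
    if (nd$kind != "input" && !all(nd$inputs %in% seen))
      msg <- c(msg, sprintf(
        "node '%s' consumes a node not defined before it (graph must be in topological order)",
        nd$name))
    seen <- c(seen, nd$name)
  }
  if (length(object@inputSize) != 1 || object@inputSize < 1)
    msg <- c(msg, "inputSize must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Training configuration
#'
#' Optimizer recipe for [trainNetwork()]: Adam with a constant learning rate,
#' mean-squared-error cost, dropout, and exponential-moving-average shadow
#' weights maintained for evaluation.
#'
#' @slot epochs integer, passes over the training set (default 3).
#' @slot learningRate numeric, constant Adam step size (default 1e-3).
#' @slot adamBeta1,adamBeta2,adamEpsilon Adam moment decay rates and
#'   stabilizer (defaults 0.9, 0.999, 1e-8).
#' @slot batchSize integer (default 64).
#' @slot dropoutKeep numeric in (0, 1], keep probability of the dropout layer
#'   on the wide fully connected activations (default 0.65).
#' @slot emaDecay numeric in [0, 1), asymptotic decay of the evaluation-time
#'   exponential moving average of the weights (default 0.999; warmed up as
#'   `min(emaDecay, (1 + t) / (10 + t))` at step t).
#' @slot seed integer, fixes shuffling, initialization and dropout masks.
#' @seealso [trainConfig()], [trainNetwork()]
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  epochs = "integer", learningRate = "numeric", adamBeta1 = "numeric",
  adamBeta2 = "numeric", adamEpsilon = "numeric", batchSize = "integer",
  dropoutKeep = "numeric", emaDecay = "numeric", seed = "integer"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1) msg <- c(msg, "epochs must be >= 1")
  if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
  if (object@dropoutKeep <= 0 || object@dropoutKeep > 1)
    msg <- c(msg, "dropoutKeep must be in (0, 1]")
  if (object@emaDecay < 0 || object@emaDecay >= 1)
    msg <- c(msg, "emaDecay must be in [0, 1)")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Trained counting model
#'
#' @slot spec the [NetworkSpec-class] that was trained.
#' @slot params named list of parameter arrays (convolution kernels, fully
#'   connected weights and biases, batchnorm scale/shift and running
#'   statistics).
#' @slot emaParams exponential-moving-average shadow copy of the trainable
#'   parameters, used for evaluation-time forwards.
#' @slot history numeric vector of per-step training MSE.
#' @slot config the [TrainConfig-class] used.
#' @seealso [trainNetwork()], [predictCounts()]
#' @exportClass TrainedModel
setClass("TrainedModel", representation(
  spec = "NetworkSpec", params = "list", emaParams = "list",
  history = "numeric", config = "TrainConfig"
))

#' Area-based counter configuration
#'
#' The area baseline segments fruit pixels by thresholding the chroma planes
#' of the YCbCr transform (red/orange fruit have high Cr and low Cb), cleans
#' the mask with mathematical morphology, and divides the total fruit area by
#' a calibrated per-fruit unit area to obtain a count.
#'
#' @slot crMin numeric, minimum Cr value (0-255 axis) of a fruit pixel.
#' @slot cbMax numeric, maximum Cb value of a fruit pixel.
#' @slot morphologyPlan list of steps, each `list(op = "opening"|"closing",
#'   radius = <pixels>)`, applied in order with a disc structuring element.
#' @slot unitArea numeric, calibrated pixel coverage of one fruit (NA until
#'   calibrated).
#' @seealso [areaBaselineConfig()], [segmentFruitMask()], [areaCount()],
#'   [calibrateUnitArea()]
#' @exportClass AreaBaselineConfig
setClass("AreaBaselineConfig", representation(
  crMin = "numeric", cbMax = "numeric", morphologyPlan = "list",
  unitArea = "numeric"
))

setValidity("AreaBaselineConfig", function(object) {
  msg <- character()
  if (object@crMin < 0 || object@crMin > 255 ||
      object@cbMax < 0 || object@cbMax > 255)
    msg <- c(msg, "chroma thresholds must be in [0, 255]")
  for (stp in object@morphologyPlan) {
    if (!stp$op %in% c("opening", "closing"))
      msg <- c(msg, "morphology ops must be 'opening' or 'closing'")
    if (stp$radius < 1) msg <- c(msg, "structuring radii must be >= 1")
  }
  if (!is.na(object@unitArea) && object@unitArea <= 0)
    msg <- c(msg, "unitArea must be positive")
  if (length(msg)) msg else TRUE
})

#' Predicted-versus-actual linear regression fit
#'
#' @slot slope,intercept ordinary-least-squares coefficients of predicted
#'   count on actual count.
#' @slot rSquared coefficient of determination, `1 - SS_res / SS_tot`.
#' @exportClass RegressionFit
setClass("RegressionFit", representation(
  slope = "numeric", intercept = "numeric", rSquared = "numeric"
))

setValidity("RegressionFit", function(object) {
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    "rSquared cannot exceed 1" else TRUE
})

#' Evaluation report for one counting method
#'
#' Per-image records and their aggregates.  Each record holds the predicted
#' count `pc`, the actual count `ac`, and the per-image relative accuracy
#' `pa = (1 - |pc - ac| / |ac|) * 100`, which is not clamped and can be
#' negative when the error exceeds the actual count.
#'
#' @slot records data.frame with columns `path`, `ac`, `pc`, `pa`.
#' @slot meanAccuracy numeric, arithmetic mean of `pa` (percent).
#' @slot mse,rmse mean squared error of the counts and its square root.
#' @slot fit a [RegressionFit-class] of predicted on actual counts.
#' @slot methodName character label used in comparison tables.
#' @seealso [evaluatePredictor()], [compareMethods()]
#' @exportClass EvalReport
setClass("EvalReport", representation(
  records = "data.frame", meanAccuracy = "numeric", mse = "numeric",
  rmse = "numeric", fit = "RegressionFit", methodName = "character"
))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (!all(c("ac", "pc", "pa") %in% names(object@records)))
    msg <- c(msg, "records must have columns ac, pc, pa")
  if (is.finite(object@mse) &&
      abs(object@rmse - sqrt(object@mse)) > 1e-8 * (1 + object@rmse))
    msg <- c(msg, "rmse must equal sqrt(mse)")
  if (length(msg)) msg else TRUE
})

#' Pipeline run configuration
#'
#' Bundles the scene, network, training and baseline configurations with the
#' output locations and a master seed so a full generate/train/evaluate/
#' compare run is reproducible from one object.
#'
#' @slot scene a [SceneConfig-class].
#' @slot train a [TrainConfig-class].
#' @slot widthMultiplier numeric, channel scaling of the deep network.
#' @slot nTrain,nTest integer, images per split.
#' @slot baseline an [AreaBaselineConfig-class] (unitArea may be NA; it is
#'   calibrated during the run).
#' @slot nCalibration integer, scenes used to calibrate the area baseline.
#' @slot outDir character, output directory.
#' @slot seed integer master seed.
#' @slot profile character, the profile this configuration was built from.
#' @seealso [runConfig()], [runPipeline()]
#' @exportClass RunConfig
setClass("RunConfig", representation(
  scene = "SceneConfig", train = "TrainConfig", widthMultiplier = "numeric",
  nTrain = "integer", nTest = "integer", baseline = "AreaBaselineConfig",
  nCalibration = "integer", outDir = "character", seed = "integer",
  profile = "character"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@nTrain < 1 || object@nTest < 1)
    msg <- c(msg, "nTrain and nTest must be >= 1")
  if (object@widthMultiplier <= 0)
    msg <- c(msg, "widthMultiplier must be positive")
  if (length(msg)) msg else TRUE
})
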