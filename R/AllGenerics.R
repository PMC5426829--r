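#' @name accessors
#' @title Accessors for glanceCount objects
#' @description Small accessor layer so downstream code never reaches into
#'   slots directly.
#' @param object a glanceCount S4 object.
#' @return The corresponding component; see the individual methods.
NULL

#' @describeIn accessors exact fruit count of a rendered scene.
#' @export
setGeneric("fruitCount", function(object) standardGeneric("fruitCount"))
setMethod("fruitCount", "LabeledScene", function(object) object@count)

#' @describeIn accessors per-fruit records (center, radius, ripeness,
#'   visible fraction) of a rendered scene.
#' @export
setGeneric("sceneFruits", function(object) standardGeneric("sceneFruits"))
setMethod("sceneFruits", "LabeledScene", function(object) object@fruits)

#' @describeIn accessors 8-bit RGB pixel array of a rendered scene.
#' @export
setGeneric("scenePixels", function(object) standardGeneric("scenePixels"))
setMethod("scenePixels", "LabeledScene", function(object) object@pixels)

#' @describeIn accessors `data.frame` of (path, count) entries of a manifest.
#' @export
setGeneric("manifestEntries",
           function(object) standardGeneric("manifestEntries"))
setMethod("manifestEntries", "DatasetManifest",
          function(object) object@entries)

#' @describeIn accessors node list of a network architecture.
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
setMethod("networkNodes", "NetworkSpec", function(object) object@nodes)

#' @describeIn accessors per-step training MSE of a trained model.
#' @export
setGeneric("trainingHistory",
           function(object) standardGeneric("trainingHistory"))
setMethod("trainingHistory", "TrainedModel", function(object) object@history)

#' @describeIn accessors evaluation-time (EMA) parameters of a trained model.
#' @export
setGeneric("emaParameters", function(object) standardGeneric("emaParameters"))
setMethod("emaParameters", "TrainedModel", function(object) object@emaParams)

#' @describeIn accessors raw (non-EMA) parameters of a trained model.
#' @export
setGeneric("modelParameters",
           function(object) standardGeneric("modelParameters"))
setMethod("modelParameters", "TrainedModel", function(object) object@params)

#' @describeIn accessors per-image records of an evaluation report.
#' @export
setGeneric("reportRecords", function(object) standardGeneric("reportRecords"))
setMethod("reportRecords", "EvalReport", function(object) object@records)

#' @describeIn accessors mean per-image accuracy (percent) of a report.
#' @export
setGeneric("meanAccuracy", function(object) standardGeneric("meanAccuracy"))
setMethod("meanAccuracy", "EvalReport", function(object) object@meanAccuracy)

#' @describeIn accessors count mean squared error of a report.
#' @export
setGeneric("countMSE", function(object) standardGeneric("countMSE"))
setMethod("countMSE", "EvalReport", function(object) object@mse)

#' @describeIn accessors count root mean squared error of a report.
#' @export
setGeneric("countRMSE", function(object) standardGeneric("countRMSE"))
setMethod("countRMSE", "EvalReport", function(object) object@rmse)

#' @describeIn accessors predicted-versus-actual regression fit of a report.
#' @export
setGeneric("regressionFit", function(object) standardGeneric("regressionFit"))
setMethod("regressionFit", "EvalReport", function(object) object@fit)

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %d x %d px, counts [%d, %d], radii [%.3f, %.3f] of side\n",
    object@imageSize, object@imageSize, object@countRange[1],
    object@countRange[2], object@radiusRange[1], object@radiusRange[2]))
  cat(sprintf(
    "  blobs [%d, %d], blur sigma %.2f, illumination %.2f, shadow p %.2f, occluder p %.2f, min visible %.2f\n",
    object@blobCountRange[1], object@blobCountRange[2], object@blurSigma,
    object@illumAmplitude, object@shadowProb, object@occluderProb,
    object@minVisibleFraction))
})

setMethod("show", "LabeledScene", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("LabeledScene: %d x %d px, count = %d (seed %d)\n",
              d[1], d[2], object@count, object@seed))
})

setMethod("show", "DatasetManifest", function(object) {
  cat(sprintf("DatasetManifest '%s': %d images (seed %d)\n",
              object@splitName, nrow(object@entries), object@seed))
})

setMethod("show", "NetworkSpec", function(object) {
  kinds <- vapply(object@nodes, `[[`, "", "kind")
  cat(sprintf("NetworkSpec '%s': %d nodes, input %d x %d x 3, width x%.2f\n",
              object@name, length(object@nodes), object@inputSize,
              object@inputSize, object@widthMultiplier))
  tab <- table(kinds)
  cat("  ", paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                  collapse = " "), "\n")
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel on '%s': %d steps, final training MSE %.3f\n",
              object@spec@name, length(object@history),
              utils::tail(object@history, 1)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport '%s': %d images, mean accuracy %.2f%%, MSE %.3f, RMSE %.3f, R^2 %.3f\n",
    object@methodName, nrow(object@records), object@meanAccuracy,
    object@mse, object@rmse, object@fit@rSquared))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig (profile '%s'): %d train / %d test, %d px, width x%.2f, seed %d\n",
    object@profile, object@nTrain, object@nTest, object@scene@imageSize,
    object@widthMultiplier, object@seed))
})
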