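# Evaluation statistics: per-image relative accuracy, MSE/RMSE, and
# predicted-versus-actual linear regression, plus method comparison tables.

#' Per-image counting accuracy
#'
#' `pa = (1 - |pc - ac| / |ac|) * 100`.  The value is 100 only when the
#' predicted count equals the actual count, is symmetric in over- and
#' under-counting by the same absolute error, and is deliberately not
#' clamped: errors larger than the actual count give negative accuracies,
#' and clamping them would silently inflate means.
#'
#' @param pc predicted count(s), real-valued or rounded.
#' @param ac actual count(s), positive integers; a zero raises an error
#'   because the formula divides by `|ac|`.
#' @return accuracy in percent, vectorized over inputs.
#' @examples
#' accuracyEq1(36, 38)  # 94.74 (to 2 dp)
#' @export
accuracyEq1 <- function(pc, ac) {
  if (any(ac == 0))
    stop("accuracy is undefined for an actual count of 0; exclude or regenerate such images")
  (1 - abs(pc - ac) / abs(ac)) * 100
}

#' Ordinary least squares of predicted on actual counts
#'
#' @param pcs predicted counts.
#' @param acs actual counts (length >= 2, not all equal).
#' @return a [RegressionFit-class] with slope, intercept and
#'   `R^2 = 1 - SS_res / SS_tot`.
#' @export
linearFit <- function(pcs, acs) {
  if (length(pcs) != length(acs))
    stop("pcs and acs must have equal length")
  if (length(pcs) < 2) stop("at least two points are required")
  if (length(unique(acs)) < 2)
    stop("actual counts are all equal; the fit is degenerate")
  fit <- lm(pcs ~ acs)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((pcs - mean(pcs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  new("RegressionFit", slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]), rSquared = r2)
}

#' Evaluate a counting predictor on a dataset
#'
#' Produces one record per image (predicted count, actual count, per-image
#' accuracy) and the aggregates: mean accuracy, MSE, RMSE and the
#' predicted-versus-actual regression.  Following the reporting convention,
#' the accuracy column uses half-up-rounded predictions when `rounding` is
#' TRUE (counts are integers when reported) while MSE/RMSE always use the
#' raw real-valued predictions.
#'
#' @param predictor either a function taking a list of H x W x 3 arrays and
#'   returning a numeric vector of counts, or a function taking a single
#'   image.
#' @param data a [DatasetManifest-class] or list of
#'   `list(image =, count =)` pairs; all actual counts must be >= 1.
#' @param rounding round predictions for the accuracy column.
#' @param methodName label stored on the report.
#' @return an [EvalReport-class].
#' @export
evaluatePredictor <- function(predictor, data, rounding = TRUE,
                              methodName = "method") {
  if (is(data, "DatasetManifest")) data <- loadDataset(data)
  if (length(data) == 0) stop("no evaluation data supplied")
  ac <- vapply(data, function(s) as.numeric(s$count), 0)
  if (any(ac < 1))
    stop("an actual count below 1 was found; exclude or regenerate those images (the accuracy formula divides by the actual count)")
  images <- lapply(data, `[[`, "image")
  pc <- tryCatch(predictor(images), error = function(e) NULL)
  if (is.null(pc) || length(pc) != length(images))
    pc <- vapply(images, function(img) as.numeric(predictor(img)), 0)
  paths <- vapply(seq_along(data), function(i)
    if (!is.null(data[[i]]$path)) data[[i]]$path else sprintf("image%04d", i),
    "")
  pcAcc <- if (rounding) roundHalfUp(pc) else pc
  records <- data.frame(path = paths, ac = ac, pc = pc,
                        pa = accuracyEq1(pcAcc, ac),
                        stringsAsFactors = FALSE)
  mse <- mseLoss(pc, ac)
  new("EvalReport", records = records, meanAccuracy = mean(records$pa),
      mse = mse, rmse = sqrt(mse), fit = linearFit(pc, ac),
      methodName = methodName)
}

#' Compare evaluation reports across methods
#'
#' @param reports list of [EvalReport-class] objects for the same test
#'   split.
#' @return data.frame with columns `method`, `meanAccuracy` (percent) and
#'   `rmse`, sorted by accuracy descending.
#' @export
compareMethods <- function(reports) {
  if (length(reports) < 1) stop("at least one report is required")
  tab <- data.frame(
    method = vapply(reports, function(r) r@methodName, ""),
    meanAccuracy = vapply(reports, meanAccuracy, 0),
    rmse = vapply(reports, countRMSE, 0),
    stringsAsFactors = FALSE)
  tab[order(-tab$meanAccuracy), , drop = FALSE]
}

#' Serialize an evaluation report
#'
#' `reportToCSV` writes the per-image `path,ac,pc,pa` records;
#' `reportToJSON` writes the full report (records plus aggregates).
#'
#' @param report an [EvalReport-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
reportToCSV <- function(report, path) {
  write.csv(reportRecords(report), path, row.names = FALSE)
  invisible(path)
}

#' @rdname reportToCSV
#' @export
reportToJSON <- function(report, path) {
  fit <- regressionFit(report)
  jsonlite::write_json(
    list(method = report@methodName, meanAccuracy = meanAccuracy(report),
         mse = countMSE(report), rmse = countRMSE(report),
         fit = list(slope = fit@slope, intercept = fit@intercept,
                    rSquared = fit@rSquared),
         records = reportRecords(report)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
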