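# Training: Xavier initialization, Adam on the MSE cost, dropout,
# batchnorm, and exponential-moving-average shadow weights for evaluation.

#' Construct a training configuration
#'
#' @param epochs passes over the training set (default 3).
#' @param learningRate constant Adam step size (default 1e-3).
#' @param adamBeta1,adamBeta2,adamEpsilon Adam hyperparameters
#'   (defaults 0.9, 0.999, 1e-8).
#' @param batchSize minibatch size (default 64).
#' @param dropoutKeep keep probability of the head dropout layer
#'   (default 0.65, i.e. 65 percent of activations are randomly kept during
#'   training).
#' @param emaDecay asymptotic decay of the evaluation-weight moving average
#'   (default 0.999).
#' @param seed RNG seed fixing shuffling, initialization and dropout masks.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(epochs = 3, learningRate = 1e-3, adamBeta1 = 0.9,
                        adamBeta2 = 0.999, adamEpsilon = 1e-8,
                        batchSize = 64, dropoutKeep = 0.65,
                        emaDecay = 0.999, seed = 1) {
  obj <- new("TrainConfig", epochs = as.integer(epochs),
             learningRate = learningRate, adamBeta1 = adamBeta1,
             adamBeta2 = adamBeta2, adamEpsilon = adamEpsilon,
             batchSize = as.integer(batchSize), dropoutKeep = dropoutKeep,
             emaDecay = emaDecay, seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Xavier (Glorot) initialization of a network's parameters
#'
#' Weight arrays are drawn uniformly on \code{[-a, a]} with
#' \code{a = sqrt(6 / (fanIn + fanOut))}, which has variance
#' \code{2 / (fanIn + fanOut)} and keeps the signal scale roughly constant
#' through the layers.  Fully connected biases start at zero; batchnorm
#' scale at one and shift at exactly zero; running-statistic accumulators at
#' zero.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed RNG seed; the same seed yields an identical parameter set.
#' @return named list of parameter arrays (a "parameter set").
#' @export
xavierInit <- function(spec, seed = 1) {
  plan <- compilePlan(spec)
  withSeed(seed, function() {
    params <- list()
    for (p in plan) {
      if (p$kind == "conv") {
        cin <- p$inShape[[1]][3]; cout <- p$outShape[3]
        kk <- p$kernel[1] * p$kernel[2]
        a <- sqrt(6 / (kk * cin + kk * cout))
        params[[p$paramKey]] <- matrix(runif(cout * kk * cin, -a, a),
                                       cout, kk * cin)
      } else if (p$kind == "fc") {
        din <- prod(p$inShape[[1]]); dout <- p$outShape[3]
        a <- sqrt(6 / (din + dout))
        params[[paste0(p$name, ".W")]] <- matrix(runif(dout * din, -a, a),
                                                 dout, din)
        params[[paste0(p$name, ".b")]] <- matrix(0, dout, 1)
      } else if (p$kind == "batchnorm") {
        cc <- p$outShape[3]
        params[[paste0(p$name, ".gamma")]] <- matrix(1, cc, 1)
        params[[paste0(p$name, ".beta")]] <- matrix(0, cc, 1)
        params[[paste0(p$name, ".rmean")]] <- matrix(0, cc, 1)
        params[[paste0(p$name, ".rvar")]] <- matrix(0, cc, 1)
      }
    }
    params[[".bnT"]] <- 0
    params
  })
}

#' Mean squared error of predicted counts
#'
#' @param predictions numeric vector of real-valued predicted counts.
#' @param labels numeric vector of ground-truth counts, same length.
#' @return mean of squared differences; zero iff the vectors are equal.
#' @export
mseLoss <- function(predictions, labels) {
  if (length(predictions) == 0 || length(labels) == 0)
    stop("mseLoss needs at least one prediction/label pair")
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  mean((predictions - labels)^2)
}

#' Exponential-moving-average update of a parameter set
#'
#' Elementwise `ema' = decay * ema + (1 - decay) * params` over every array
#' in the set.  With decay 0 the result equals `params`; with decay 1 it is
#' unchanged.
#'
#' @param ema,params shape-compatible parameter sets.
#' @param decay scalar in \code{[0, 1]}.
#' @return the updated parameter set.
#' @export
emaUpdate <- function(ema, params, decay) {
  stopifnot(decay >= 0, decay <= 1)
  if (!identical(sort(names(ema)), sort(names(params))))
    stop("ema and params have different parameter keys")
  for (k in names(ema)) {
    if (!identical(dim(ema[[k]]), dim(params[[k]])) ||
        length(ema[[k]]) != length(params[[k]]))
      stop(sprintf("shape mismatch for parameter '%s'", k))
    ema[[k]] <- decay * ema[[k]] + (1 - decay) * params[[k]]
  }
  ema
}

# Load a manifest (or accept preloaded data) into the engine's pixel matrix.
datasetToMatrix <- function(data, inputSize) {
  if (is(data, "DatasetManifest")) {
    pairs <- loadDataset(data)
    list(X = imagesToMatrix(lapply(pairs, `[[`, "image"), inputSize),
         y = vapply(pairs, `[[`, 0, "count"),
         paths = vapply(pairs, `[[`, "", "path"))
  } else if (is.list(data) && !is.null(data$X)) {
    data
  } else stop("data must be a DatasetManifest or a preloaded list")
}

#' Train a counting network
#'
#' Runs `epochs * ceiling(n / batchSize)` Adam steps on the mean-squared-
#' error cost with Xavier-initialized weights, dropout at the configured
#' keep probability, batch normalization, and an exponential moving average
#' of the weights maintained after every step for evaluation-time forwards.
#' The EMA decay is warmed up as `min(emaDecay, (1 + t) / (10 + t))` so that
#' short schedules are not dominated by the random initialization.  A fixed
#' seed fixes shuffling, initialization and dropout masks, making the loss
#' history reproducible.
#'
#' @param spec a [NetworkSpec-class].
#' @param trainData a [DatasetManifest-class] (or preloaded list with
#'   elements `X`, `y` as built internally).
#' @param valData optional held-out manifest; when supplied the final
#'   validation MSE (EMA weights) is recorded in the returned model's
#'   history attributes.
#' @param config a [TrainConfig-class].
#' @param verbose print per-epoch progress.
#' @return a [TrainedModel-class].
#' @export
trainNetwork <- function(spec, trainData, valData = NULL,
                         config = trainConfig(), verbose = FALSE) {
  validObject(config)
  plan <- compilePlan(spec)
  tr <- datasetToMatrix(trainData, spec@inputSize)
  n <- length(tr$y)
  if (n < 1) stop("training dataset is empty")
  y <- as.numeric(tr$y)

  params <- xavierInit(spec, config@seed)
  ema <- params
  tkeys <- names(params)[isTrainableKey(names(params))]
  mState <- lapply(params[tkeys], function(p) p * 0)
  vState <- mState

  nBatches <- ceiling(n / config@batchSize)
  totalSteps <- config@epochs * nBatches
  history <- numeric(totalSteps)
  b1 <- config@adamBeta1; b2 <- config@adamBeta2
  lr <- config@learningRate; eps <- config@adamEpsilon
  step <- 0L

  withSeed(config@seed + 1L, function() {
    for (epoch in seq_len(config@epochs)) {
      perm <- sample.int(n)
      for (bi in seq_len(nBatches)) {
        ids <- perm[(((bi - 1L) * config@batchSize) + 1L):
                      min(bi * config@batchSize, n)]
        Xb <- tr$X[, ids, drop = FALSE]
        yb <- y[ids]
        fw <- runForward(plan, params, Xb, training = TRUE,
                         keepCache = TRUE,
                         keepOverride = config@dropoutKeep)
        params <<- fw$params  # running statistics advanced
        loss <- mseLoss(fw$pred, yb)
        step <<- step + 1L
        if (!is.finite(loss))
          stop(sprintf("training diverged (non-finite loss) at step %d",
                       step))
        history[step] <<- loss
        dOut <- 2 * (fw$pred - yb) / length(yb)
        grads <- runBackward(plan, params, fw, dOut)
        for (k in tkeys) {
          g <- grads[[k]]
          if (is.null(g)) next
          mState[[k]] <<- b1 * mState[[k]] + (1 - b1) * g
          vState[[k]] <<- b2 * vState[[k]] + (1 - b2) * g * g
          mhat <- mState[[k]] / (1 - b1^step)
          vhat <- vState[[k]] / (1 - b2^step)
          params[[k]] <<- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
        }
        decay <- min(config@emaDecay, (1 + step) / (10 + step))
        ema <<- emaUpdate(ema, params, decay)
      }
      if (verbose)
        message(sprintf("epoch %d/%d: mean training MSE %.4f", epoch,
                        config@epochs,
                        mean(history[(step - nBatches + 1L):step])))
    }
  })

  model <- new("TrainedModel", spec = spec, params = params,
               emaParams = ema, history = history, config = config)
  if (!is.null(valData)) {
    va <- datasetToMatrix(valData, spec@inputSize)
    pv <- predictCounts(model, va, rounded = FALSE)
    attr(model@history, "valMSE") <- mseLoss(pv, va$y)
  }
  model
}

#' Predict counts with a trained model
#'
#' Evaluation-time forwards use the exponential-moving-average weights and
#' the running batchnorm statistics; dropout is inactive, so predictions are
#' deterministic.
#'
#' @param model a [TrainedModel-class].
#' @param data a [DatasetManifest-class], a list of H x W x 3 arrays, or a
#'   preloaded list with an `X` matrix.
#' @param rounded round predictions half-up to integers (the reporting
#'   convention); FALSE returns the raw network output used for MSE/RMSE.
#' @param useEma use the EMA shadow weights (default) rather than the raw
#'   final weights.
#' @param batchSize forward batch size.
#' @return numeric vector of predicted counts.
#' @export
predictCounts <- function(model, data, rounded = FALSE, useEma = TRUE,
                          batchSize = 64) {
  spec <- model@spec
  plan <- compilePlan(spec)
  params <- if (useEma) model@emaParams else model@params
  X <- if (is.list(data) && !is.null(data$X)) data$X
       else if (is(data, "DatasetManifest"))
         datasetToMatrix(data, spec@inputSize)$X
       else imagesToMatrix(data, spec@inputSize)
  n <- ncol(X)
  preds <- numeric(n)
  for (start in seq(1, n, by = batchSize)) {
    ids <- start:min(start + batchSize - 1, n)
    preds[ids] <- runForward(plan, params, X[, ids, drop = FALSE],
                             training = FALSE)$pred
  }
  if (rounded) roundHalfUp(preds) else preds
}

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds the architecture as JSON, the parameter and
#' EMA arrays in an R data serialization, and the training history as a
#' `step,mse` CSV.
#'
#' @param model a [TrainedModel-class].
#' @param dir checkpoint directory (created if missing).
#' @return `saveCheckpoint` returns `dir` invisibly; `loadCheckpoint`
#'   returns the restored [TrainedModel-class].
#' @export
saveCheckpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  networkToJSON(model@spec, file.path(dir, "spec.json"))
  saveRDS(list(params = model@params, emaParams = model@emaParams,
               config = model@config), file.path(dir, "params.rds"))
  write.csv(data.frame(step = seq_along(model@history),
                       mse = as.numeric(model@history)),
            file.path(dir, "history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) {
  spec <- networkFromJSON(file.path(dir, "spec.json"))
  blob <- readRDS(file.path(dir, "params.rds"))
  hist <- read.csv(file.path(dir, "history.csv"))
  new("TrainedModel", spec = spec, params = blob$params,
      emaParams = blob$emaParams, history = as.numeric(hist$mse),
      config = blob$config)
}
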