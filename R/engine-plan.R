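# Graph compilation and forward/backward execution for NetworkSpec objects.
#
# Activations live as (H*W*C) x N matrices with the layout documented in
# src/engine.cpp, so `flatten` is the identity and channel concatenation is
# a row-bind.  The compiled plan annotates every node with input/output
# shapes, padding amounts and parameter keys; it is computed once per spec
# and reused for every batch.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

# Annotate every node with shapes and padding; errors name the offending
# node.  Returns a list of plan nodes (same order as spec@nodes).
compilePlan <- function(spec) {
  stopifnot(is(spec, "NetworkSpec"))
  validObject(spec)
  nodes <- spec@nodes
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  idx <- stats::setNames(seq_along(nodes), names(nodes))
  plan <- vector("list", length(nodes))
  shapes <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    p <- list(name = nd$name, kind = nd$kind,
              inIdx = if (nd$kind == "input") integer() else
                unname(idx[nd$inputs]))
    inShape <- lapply(p$inIdx, function(j) shapes[[j]])
    out <- switch(nd$kind,
      input = c(spec@inputSize, spec@inputSize, 3L),
      conv = {
        s <- inShape[[1]]
        k <- nd$kernel; st <- nd$stride
        if (identical(nd$padding, "SAME")) {
          ho <- ceiling(s[1] / st); wo <- ceiling(s[2] / st)
          padH <- max((ho - 1L) * st + k[1] - s[1], 0L)
          padW <- max((wo - 1L) * st + k[2] - s[2], 0L)
          p$padt <- padH %/% 2L; p$padl <- padW %/% 2L
        } else {
          ho <- floor((s[1] - k[1]) / st) + 1L
          wo <- floor((s[2] - k[2]) / st) + 1L
          p$padt <- 0L; p$padl <- 0L
        }
        if (ho < 1 || wo < 1)
          stop(sprintf("node '%s': input %dx%d too small for kernel/stride",
                       nd$name, s[1], s[2]))
        p$kernel <- as.integer(k); p$stride <- as.integer(st)
        p$paramKey <- paste0(nd$name, ".W")
        c(as.integer(ho), as.integer(wo), as.integer(nd$outChannels))
      },
      batchnorm = { p$paramKey <- nd$name; inShape[[1]] },
      relu = inShape[[1]],
      maxpool = ,
      avgpool = {
        s <- inShape[[1]]
        k <- nd$kernel; st <- nd$stride
        ho <- floor((s[1] - k[1]) / st) + 1L
        wo <- floor((s[2] - k[2]) / st) + 1L
        if (ho < 1 || wo < 1)
          stop(sprintf("node '%s': input %dx%d too small for pooling window",
                       nd$name, s[1], s[2]))
        p$kernel <- as.integer(k); p$stride <- as.integer(st)
        c(as.integer(ho), as.integer(wo), s[3])
      },
      fc = { p$paramKey <- nd$name
             c(1L, 1L, as.integer(nd$outChannels)) },
      dropout = { p$keep <- nd$keep; inShape[[1]] },
      flatten = { s <- inShape[[1]]; c(1L, 1L, as.integer(prod(s))) },
      concat = {
        hs <- vapply(inShape, `[`, 0L, 1)
        ws <- vapply(inShape, `[`, 0L, 2)
        if (length(unique(hs)) > 1 || length(unique(ws)) > 1)
          stop(sprintf("node '%s': concat operands differ spatially",
                       nd$name))
        c(inShape[[1]][1], inShape[[1]][2],
          sum(vapply(inShape, `[`, 0L, 3)))
      },
      add = {
        if (!identical(inShape[[1]], inShape[[2]]))
          stop(sprintf(
            "node '%s': residual operands have mismatched shapes %s vs %s",
            nd$name, paste(inShape[[1]], collapse = "x"),
            paste(inShape[[2]], collapse = "x")))
        p$scale <- if (is.null(nd$scale)) 1 else nd$scale
        inShape[[1]]
      },
      stop(sprintf("node '%s': unknown kind '%s'", nd$name, nd$kind))
    )
    p$inShape <- inShape
    p$outShape <- out
    shapes[[i]] <- out
    plan[[i]] <- p
  }
  # fuse batchnorm -> relu pairs: the rectifier is applied inside the
  # batchnorm kernel and the relu node becomes an alias of its input
  consumers <- vector("list", length(plan))
  for (i in seq_along(plan))
    for (j in plan[[i]]$inIdx)
      consumers[[j]] <- c(consumers[[j]], i)
  for (i in seq_along(plan)) {
    if (plan[[i]]$kind == "batchnorm" && length(consumers[[i]]) == 1 &&
        plan[[consumers[[i]]]]$kind == "relu") {
      plan[[i]]$fuseRelu <- TRUE
      plan[[consumers[[i]]]]$fusedFrom <- i
    }
  }
  names(plan) <- names(nodes)
  plan
}

# Trainable and state array dimensions implied by a plan, keyed the way
# ParameterSet lists are.
paramTemplate <- function(plan) {
  tpl <- list()
  for (p in plan) {
    if (p$kind == "conv") {
      cin <- p$inShape[[1]][3]
      tpl[[p$paramKey]] <- c(p$outShape[3], p$kernel[1] * p$kernel[2] * cin)
    } else if (p$kind == "fc") {
      tpl[[paste0(p$name, ".W")]] <- c(p$outShape[3], prod(p$inShape[[1]]))
      tpl[[paste0(p$name, ".b")]] <- c(p$outShape[3], 1)
    } else if (p$kind == "batchnorm") {
      cc <- p$outShape[3]
      tpl[[paste0(p$name, ".gamma")]] <- c(cc, 1)
      tpl[[paste0(p$name, ".beta")]] <- c(cc, 1)
      tpl[[paste0(p$name, ".rmean")]] <- c(cc, 1)
      tpl[[paste0(p$name, ".rvar")]] <- c(cc, 1)
    }
  }
  tpl
}

isTrainableKey <- function(keys)
  grepl("\\.(W|b|gamma|beta)$", keys)

# Debiased running moments for inference.  Accumulators start at zero and
# are divided by (1 - momentum^t) so short schedules still yield calibrated
# statistics; before any training step the identity transform statistics
# (mean 0, variance 1) are used.
bnInferStats <- function(params, key) {
  t <- params[[".bnT"]]
  if (is.null(t) || t <= 0)
    return(list(mean = params[[paste0(key, ".rmean")]] * 0,
                var = params[[paste0(key, ".rvar")]] * 0 + 1))
  f <- 1 - BN_MOMENTUM^t
  list(mean = params[[paste0(key, ".rmean")]] / f,
       var = pmax(params[[paste0(key, ".rvar")]] / f, 0))
}

# Forward pass.  X is (S*S*3) x N in [0, 1].  In training mode batch
# statistics are used (and running statistics updated), and dropout draws
# masks from the current R RNG stream.  Returns predictions, per-node
# activations/caches (when keepCache) and the possibly updated params.
runForward <- function(plan, params, X, training = FALSE,
                       keepCache = FALSE, keepOverride = NULL) {
  n <- length(plan)
  outs <- vector("list", n)
  caches <- if (keepCache) vector("list", n) else NULL
  for (i in seq_len(n)) {
    p <- plan[[i]]
    out <- switch(p$kind,
      input = X,
      conv = {
        s <- p$inShape[[1]]
        cpp_conv_forward(outs[[p$inIdx]], s[1], s[2], s[3],
                         params[[p$paramKey]], p$kernel[1], p$kernel[2],
                         p$stride, p$padt, p$padl,
                         p$outShape[1], p$outShape[2])
      },
      batchnorm = {
        s <- p$inShape[[1]]
        hw <- s[1] * s[2]
        g <- as.numeric(params[[paste0(p$name, ".gamma")]])
        b <- as.numeric(params[[paste0(p$name, ".beta")]])
        fuse <- isTRUE(p$fuseRelu)
        if (training) {
          r <- cpp_bn_forward(outs[[p$inIdx]], hw, s[3], g, b, BN_EPS,
                              relu = fuse)
          params[[paste0(p$name, ".rmean")]] <-
            BN_MOMENTUM * params[[paste0(p$name, ".rmean")]] +
            (1 - BN_MOMENTUM) * r$mean
          params[[paste0(p$name, ".rvar")]] <-
            BN_MOMENTUM * params[[paste0(p$name, ".rvar")]] +
            (1 - BN_MOMENTUM) * r$var
          if (keepCache) caches[[i]] <- list(mean = r$mean, var = r$var)
          r$Y
        } else {
          st <- bnInferStats(params, p$name)
          cpp_bn_infer(outs[[p$inIdx]], hw, s[3], g, b,
                       as.numeric(st$mean), as.numeric(st$var), BN_EPS,
                       relu = fuse)
        }
      },
      relu = if (!is.null(p$fusedFrom)) outs[[p$inIdx]]
             else cpp_relu_forward(outs[[p$inIdx]]),
      maxpool = {
        s <- p$inShape[[1]]
        r <- cpp_maxpool_forward(outs[[p$inIdx]], s[1], s[2], s[3],
                                 p$kernel[1], p$kernel[2], p$stride,
                                 p$outShape[1], p$outShape[2])
        if (keepCache) caches[[i]] <- list(idx = r$idx)
        r$Y
      },
      avgpool = {
        s <- p$inShape[[1]]
        cpp_avgpool_forward(outs[[p$inIdx]], s[1], s[2], s[3],
                            p$kernel[1], p$kernel[2], p$stride,
                            p$outShape[1], p$outShape[2])
      },
      fc = params[[paste0(p$name, ".W")]] %*% outs[[p$inIdx]] +
           as.numeric(params[[paste0(p$name, ".b")]]),
      dropout = {
        keep <- if (is.null(keepOverride)) p$keep else keepOverride
        xin <- outs[[p$inIdx]]
        if (training && keep < 1) {
          mask <- matrix(as.numeric(runif(length(xin)) < keep) / keep,
                         nrow(xin), ncol(xin))
          if (keepCache) caches[[i]] <- list(mask = mask)
          xin * mask
        } else xin
      },
      flatten = outs[[p$inIdx]],
      concat = do.call(rbind, outs[p$inIdx]),
      add = cpp_axpy(outs[[p$inIdx[1]]], outs[[p$inIdx[2]]], p$scale)
    )
    outs[[i]] <- out
  }
  if (training) params[[".bnT"]] <- (params[[".bnT"]] %||% 0) + 1
  list(pred = as.numeric(outs[[n]]), outs = outs, caches = caches,
       params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backward pass through a cached forward.  dOut is the gradient of the loss
# with respect to the scalar outputs (length N).  Returns gradients keyed
# like the trainable parameters.
runBackward <- function(plan, params, fw, dOut) {
  n <- length(plan)
  outs <- fw$outs
  caches <- fw$caches
  gradOut <- vector("list", n)
  gradOut[[n]] <- matrix(dOut, nrow = 1)
  grads <- list()
  addG <- function(j, g) {
    gradOut[[j]] <<- if (is.null(gradOut[[j]])) g else gradOut[[j]] + g
  }
  for (i in rev(seq_len(n))) {
    p <- plan[[i]]
    g <- gradOut[[i]]
    if (is.null(g)) next
    switch(p$kind,
      input = NULL,
      conv = {
        s <- p$inShape[[1]]
        r <- cpp_conv_backward(outs[[p$inIdx]], g, params[[p$paramKey]],
                               s[1], s[2], s[3], p$kernel[1], p$kernel[2],
                               p$stride, p$padt, p$padl,
                               p$outShape[1], p$outShape[2])
        grads[[p$paramKey]] <- r$dW
        addG(p$inIdx, r$dX)
      },
      batchnorm = {
        s <- p$inShape[[1]]
        cc <- caches[[i]]
        r <- cpp_bn_backward(outs[[p$inIdx]], outs[[i]], g, s[1] * s[2],
                             s[3],
                             as.numeric(params[[paste0(p$name, ".gamma")]]),
                             cc$mean, cc$var, BN_EPS,
                             relu = isTRUE(p$fuseRelu))
        grads[[paste0(p$name, ".gamma")]] <- matrix(r$dgamma)
        grads[[paste0(p$name, ".beta")]] <- matrix(r$dbeta)
        addG(p$inIdx, r$dX)
      },
      relu = if (!is.null(p$fusedFrom)) addG(p$inIdx, g)
             else addG(p$inIdx, cpp_relu_backward(g, outs[[i]])),
      maxpool = {
        s <- p$inShape[[1]]
        addG(p$inIdx, cpp_maxpool_backward(g, caches[[i]]$idx,
                                           prod(s)))
      },
      avgpool = {
        s <- p$inShape[[1]]
        addG(p$inIdx, cpp_avgpool_backward(g, s[1], s[2], s[3],
                                           p$kernel[1], p$kernel[2],
                                           p$stride, p$outShape[1],
                                           p$outShape[2]))
      },
      fc = {
        xin <- outs[[p$inIdx]]
        grads[[paste0(p$name, ".W")]] <- g %*% t(xin)
        grads[[paste0(p$name, ".b")]] <- matrix(rowSums(g))
        addG(p$inIdx, crossprod(params[[paste0(p$name, ".W")]], g))
      },
      dropout = {
        m <- caches[[i]]$mask
        addG(p$inIdx, if (is.null(m)) g else g * m)
      },
      flatten = addG(p$inIdx, g),
      concat = {
        row0 <- 0L
        for (j in seq_along(p$inIdx)) {
          nr <- prod(p$inShape[[j]])
          addG(p$inIdx[j], g[(row0 + 1L):(row0 + nr), , drop = FALSE])
          row0 <- row0 + nr
        }
      },
      add = {
        addG(p$inIdx[1], g)
        addG(p$inIdx[2], if (p$scale == 1) g else p$scale * g)
      }
    )
    gradOut[[i]] <- NULL
    caches[[i]] <- NULL
    if (p$kind != "input") outs[[i]] <- NULL
  }
  grads
}

# Convert a batch of images (list of H x W x 3 arrays, or one array, or a
# H x W x 3 x N array) to the engine's (H*W*C) x N matrix in [0, 1].
imagesToMatrix <- function(images, inputSize) {
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  if (is.array(images) && length(dim(images)) == 4) {
    d <- dim(images)
    images <- lapply(seq_len(d[4]), function(i) images[, , , i])
  }
  X <- vapply(images, function(img) {
    d <- dim(img)
    if (length(d) != 3 || d[3] != 3)
      stop("each image must be an H x W x 3 array")
    if (d[1] != inputSize || d[2] != inputSize)
      stop(sprintf("image is %dx%d but the network expects %dx%d",
                   d[1], d[2], inputSize, inputSize))
    v <- as.numeric(img)
    if (max(v) > 1.5) v <- v / 255
    v
  }, numeric(inputSize * inputSize * 3L))
  matrix(X, ncol = length(images))
}
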