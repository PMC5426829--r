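# Declarative architecture definitions: the modified Inception-ResNet
# counting network and the shallow two-conv/two-fc baseline.

nodeConv <- function(name, input, k, outChannels, stride = 1L,
                     padding = "SAME") {
  list(name = name, kind = "conv", inputs = input,
       kernel = as.integer(c(k, k)), stride = as.integer(stride),
       padding = padding, outChannels = as.integer(outChannels))
}
nodeBN <- function(name, input) list(name = name, kind = "batchnorm",
                                     inputs = input)
nodeReLU <- function(name, input) list(name = name, kind = "relu",
                                       inputs = input)
nodePool <- function(name, input, kind, k, stride)
  list(name = name, kind = kind, inputs = input,
       kernel = as.integer(c(k, k)), stride = as.integer(stride),
       padding = "VALID")
nodeFC <- function(name, input, outChannels)
  list(name = name, kind = "fc", inputs = input,
       outChannels = as.integer(outChannels))
nodeDropout <- function(name, input, keep)
  list(name = name, kind = "dropout", inputs = input, keep = keep)
nodeFlatten <- function(name, input)
  list(name = name, kind = "flatten", inputs = input)
nodeConcat <- function(name, inputs)
  list(name = name, kind = "concat", inputs = inputs)
nodeAdd <- function(name, a, b, scale = 1)
  list(name = name, kind = "add", inputs = c(a, b), scale = scale)

# conv -> batchnorm [-> relu]; returns the nodes and the output node name.
convBlock <- function(prefix, input, k, outChannels, stride = 1L,
                      padding = "SAME", relu = TRUE) {
  nodes <- list(
    nodeConv(paste0(prefix, "_conv"), input, k, outChannels, stride,
             padding),
    nodeBN(paste0(prefix, "_bn"), paste0(prefix, "_conv")))
  out <- paste0(prefix, "_bn")
  if (relu) {
    nodes <- c(nodes, list(nodeReLU(paste0(prefix, "_relu"), out)))
    out <- paste0(prefix, "_relu")
  }
  list(nodes = nodes, out = out)
}

#' Modified Inception-ResNet-A block (expanded to primitive nodes)
#'
#' Three parallel branches (1x1; 1x1 then 3x3; 1x1 then two 3x3) are
#' concatenated and linearly projected by a 1x1 convolution back to the
#' block's input channel count, scaled, added to the block input, and
#' rectified.  Branch widths follow the Inception-ResNet-v1 defaults scaled
#' by the width multiplier; the projection width is forced to the input
#' channel count so the residual addition is shape-compatible.
#'
#' @param prefix node-name prefix.
#' @param input name of the producer node.
#' @param channelsIn input channel count (also the projection width).
#' @param wm width multiplier applied to branch widths.
#' @param residualScale scalar on the projected branch before the addition.
#' @return list with `nodes` (primitive node list) and `out` (output node
#'   name).
#' @keywords internal
#' @noRd
aModule <- function(prefix, input, channelsIn, wm = 1, residualScale = 1) {
  ch <- function(x) max(1L, as.integer(round(x * wm)))
  b1 <- convBlock(paste0(prefix, "_b1a"), input, 1, ch(32))
  b2a <- convBlock(paste0(prefix, "_b2a"), input, 1, ch(32))
  b2b <- convBlock(paste0(prefix, "_b2b"), b2a$out, 3, ch(32))
  b3a <- convBlock(paste0(prefix, "_b3a"), input, 1, ch(32))
  b3b <- convBlock(paste0(prefix, "_b3b"), b3a$out, 3, ch(48))
  b3c <- convBlock(paste0(prefix, "_b3c"), b3b$out, 3, ch(64))
  cat_ <- nodeConcat(paste0(prefix, "_concat"),
                     c(b1$out, b2b$out, b3c$out))
  # linear projection: batchnorm but no rectification before the residual sum
  proj <- convBlock(paste0(prefix, "_proj"), paste0(prefix, "_concat"), 1,
                    channelsIn, relu = FALSE)
  addn <- nodeAdd(paste0(prefix, "_add"), input, proj$out,
                  scale = residualScale)
  outr <- nodeReLU(paste0(prefix, "_relu"), paste0(prefix, "_add"))
  list(nodes = c(b1$nodes, b2a$nodes, b2b$nodes, b3a$nodes, b3b$nodes,
                 b3c$nodes, list(cat_), proj$nodes, list(addn, outr)),
       out = paste0(prefix, "_relu"))
}

# Modified reduction block: max pool | 1x1 -> strided 3x3 (128) |
# 1x1 (192) -> 3x3 (128) -> 3x3 (128) -> strided 3x3 (128); stride-2 stages
# are unpadded, so the spatial extent is halved and the channel count grows
# by 256 (at width multiplier 1).
reductionModule <- function(prefix, input, wm = 1) {
  ch <- function(x) max(1L, as.integer(round(x * wm)))
  left <- nodePool(paste0(prefix, "_pool"), input, "maxpool", 3, 2)
  m1 <- convBlock(paste0(prefix, "_m1"), input, 1, ch(128))
  m2 <- convBlock(paste0(prefix, "_m2"), m1$out, 3, ch(128), stride = 2,
                  padding = "VALID")
  r1 <- convBlock(paste0(prefix, "_r1"), input, 1, ch(192))
  r2 <- convBlock(paste0(prefix, "_r2"), r1$out, 3, ch(128))
  r3 <- convBlock(paste0(prefix, "_r3"), r2$out, 3, ch(128))
  r4 <- convBlock(paste0(prefix, "_r4"), r3$out, 3, ch(128), stride = 2,
                  padding = "VALID")
  cat_ <- nodeConcat(paste0(prefix, "_concat"),
                     c(paste0(prefix, "_pool"), m2$out, r4$out))
  list(nodes = c(list(left), m1$nodes, m2$nodes, r1$nodes, r2$nodes,
                 r3$nodes, r4$nodes, list(cat_)),
       out = paste0(prefix, "_concat"),
       addedChannels = ch(128) + ch(128))
}

#' Construct a network architecture from primitive nodes
#'
#' Low-level constructor for custom graphs; [buildCountNet()] and
#' [buildShallowNet()] are the standard architectures.  Nodes must be listed
#' in topological order.
#'
#' @param nodes list of node descriptions (see [NetworkSpec-class]).
#' @param inputSize image side in pixels.
#' @param widthMultiplier channel-width scale recorded on the spec.
#' @param name architecture label.
#' @return a [NetworkSpec-class]; shapes are validated by compiling the
#'   graph, so incompatible residual operands fail here with the node named.
#' @export
networkSpec <- function(nodes, inputSize, widthMultiplier = 1,
                        name = "custom") {
  spec <- new("NetworkSpec", nodes = nodes,
              inputSize = as.integer(inputSize),
              widthMultiplier = widthMultiplier, name = name)
  compilePlan(spec)  # shape-checks the graph
  spec
}

#' Build the modified Inception-ResNet counting network
#'
#' The architecture is: 7x7 stride-2 convolution (3 RGB bands to 64 feature
#' maps) then 3x3 max pooling with stride 2; a 1x1 convolution (80) and a
#' 5x5 convolution (192) to reduce dimensionality; two modified
#' Inception-ResNet-A blocks whose final 1x1 projection calculates 192
#' features; a modified reduction block that halves the spatial extent and
#' widens the channels by 256; two further A blocks at the widened channel
#' count; then 3x3 average pooling, a 768-wide fully connected layer,
#' dropout with keep probability 0.65, and a single linear output giving the
#' predicted fruit count.  Batch normalization follows every convolution.
#' All channel widths scale with `widthMultiplier` (1 is the reference
#' network; smaller values give desk-scale builds).
#'
#' @param widthMultiplier positive channel-width scale.
#' @param inputSize image side in pixels (>= 32, so the stride schedule
#'   leaves a positive spatial extent at the head).
#' @param dropoutKeep keep probability of the head dropout node.
#' @param residualScale scalar applied to each A block's projected branch
#'   before the residual addition.
#' @return a [NetworkSpec-class].
#' @examples
#' spec <- buildCountNet(widthMultiplier = 0.25, inputSize = 32)
#' inferShapes(spec)[["head_out"]]
#' @seealso [buildShallowNet()], [forwardNetwork()], [trainNetwork()]
#' @export
buildCountNet <- function(widthMultiplier = 1, inputSize = 128,
                          dropoutKeep = 0.65, residualScale = 1) {
  stopifnot(widthMultiplier > 0)
  if (inputSize < 32)
    stop("inputSize must be >= 32 for the stride schedule")
  wm <- widthMultiplier
  ch <- function(x) max(1L, as.integer(round(x * wm)))
  nodes <- list(list(name = "input", kind = "input"))
  s1 <- convBlock("stem1", "input", 7, ch(64), stride = 2)
  pool <- nodePool("stem_pool", s1$out, "maxpool", 3, 2)
  s2 <- convBlock("stem2", "stem_pool", 1, ch(80))
  s3 <- convBlock("stem3", s2$out, 5, ch(192))
  nodes <- c(nodes, s1$nodes, list(pool), s2$nodes, s3$nodes)
  cur <- s3$out; curC <- ch(192)
  for (nm in c("a1", "a2")) {
    m <- aModule(nm, cur, curC, wm, residualScale)
    nodes <- c(nodes, m$nodes); cur <- m$out
  }
  red <- reductionModule("red", cur, wm)
  nodes <- c(nodes, red$nodes)
  cur <- red$out; curC <- curC + red$addedChannels
  for (nm in c("a3", "a4")) {
    m <- aModule(nm, cur, curC, wm, residualScale)
    nodes <- c(nodes, m$nodes); cur <- m$out
  }
  nodes <- c(nodes, list(
    nodePool("head_pool", cur, "avgpool", 3, 2),
    nodeFlatten("head_flatten", "head_pool"),
    nodeFC("head_fc1", "head_flatten", ch(768)),
    nodeReLU("head_fc1_relu", "head_fc1"),
    nodeDropout("head_dropout", "head_fc1_relu", dropoutKeep),
    nodeFC("head_out", "head_dropout", 1)))
  networkSpec(nodes, inputSize, widthMultiplier, "countnet")
}

#' Build the shallow baseline network
#'
#' A deliberately small comparison network: exactly two convolutional layers
#' and two fully connected layers (plus batch normalization after each
#' convolution, pooling and a scalar regression output).
#'
#' @param inputSize image side in pixels (>= 16).
#' @return a [NetworkSpec-class].
#' @export
buildShallowNet <- function(inputSize = 128) {
  if (inputSize < 16) stop("inputSize must be >= 16")
  c1 <- convBlock("c1", "input", 5, 16, stride = 2)
  c2 <- convBlock("c2", c1$out, 5, 32, stride = 2)
  nodes <- c(list(list(name = "input", kind = "input")), c1$nodes, c2$nodes,
             list(nodePool("pool", c2$out, "maxpool", 3, 2),
                  nodeFlatten("flatten", "pool"),
                  nodeFC("fc1", "flatten", 64),
                  nodeReLU("fc1_relu", "fc1"),
                  nodeFC("fc2", "fc1_relu", 1)))
  networkSpec(nodes, inputSize, 1, "shallow")
}

#' Infer per-node output shapes
#'
#' Walks the graph once, computing every node's output (height, width,
#' channels).  Unpadded stride-2 stages on size s give
#' `floor((s - k) / 2) + 1`; SAME-padded stages give `ceiling(s / stride)`.
#'
#' @param spec a [NetworkSpec-class].
#' @param inputSize optional override of the spec's input size.
#' @return named list of integer `c(height, width, channels)` per node.
#' @export
inferShapes <- function(spec, inputSize = NULL) {
  if (!is.null(inputSize)) spec@inputSize <- as.integer(inputSize)
  plan <- compilePlan(spec)
  lapply(plan, `[[`, "outShape")
}

#' Count trainable parameters
#'
#' Convolution kernels (bias-free; a batchnorm follows every convolution),
#' fully connected weights and biases, and batchnorm scale/shift pairs.
#' Running statistics are state, not parameters, and are excluded.
#'
#' @param spec a [NetworkSpec-class].
#' @return integer-valued numeric total.
#' @export
countParameters <- function(spec) {
  tpl <- paramTemplate(compilePlan(spec))
  tpl <- tpl[isTrainableKey(names(tpl))]
  sum(vapply(tpl, prod, 0))
}

#' Forward-evaluate a network on a batch of images
#'
#' @param spec a [NetworkSpec-class].
#' @param params a parameter list from [xavierInit()] or a trained model.
#' @param images list of H x W x 3 arrays (8-bit 0-255 or already scaled to
#'   \code{[0, 1]}), a single such array, or an H x W x 3 x N array.
#' @param trainingMode logical; when TRUE batch statistics are used for the
#'   batchnorm nodes and dropout masks are drawn from the R RNG stream, when
#'   FALSE (the default) running statistics are used, dropout is inactive
#'   and the forward is deterministic.
#' @return numeric vector, one real-valued count per image.
#' @examples
#' spec <- buildCountNet(widthMultiplier = 0.25, inputSize = 32)
#' params <- xavierInit(spec, seed = 1)
#' imgs <- replicate(2, array(sample(0:255, 32 * 32 * 3, TRUE),
#'                            c(32, 32, 3)), simplify = FALSE)
#' forwardNetwork(spec, params, imgs)
#' @export
forwardNetwork <- function(spec, params, images, trainingMode = FALSE) {
  plan <- compilePlan(spec)
  X <- imagesToMatrix(images, spec@inputSize)
  runForward(plan, params, X, training = trainingMode)$pred
}

#' Serialize a network architecture to JSON
#'
#' Architectures are stored as a plain node list so they can be diffed and
#' rebuilt without any learning framework.
#'
#' @param spec a [NetworkSpec-class].
#' @param path optional file to write; when NULL the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
networkToJSON <- function(spec, path = NULL) {
  js <- jsonlite::toJSON(
    list(name = spec@name, inputSize = spec@inputSize,
         widthMultiplier = spec@widthMultiplier, nodes = spec@nodes),
    auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname networkToJSON
#' @param json a JSON string or path to a JSON file produced by
#'   [networkToJSON()].
#' @export
networkFromJSON <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  nodes <- lapply(obj$nodes, function(nd) {
    nd$inputs <- as.character(unlist(nd$inputs))
    if (!is.null(nd$kernel)) nd$kernel <- as.integer(unlist(nd$kernel))
    if (!is.null(nd$stride)) nd$stride <- as.integer(nd$stride)
    if (!is.null(nd$outChannels))
      nd$outChannels <- as.integer(nd$outChannels)
    nd
  })
  networkSpec(nodes, obj$inputSize, obj$widthMultiplier, obj$name)
}
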