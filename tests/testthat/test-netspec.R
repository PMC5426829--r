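nodeKinds <- function(spec) vapply(networkNodes(spec), `[[`, "", "kind")
nodeByName <- function(spec, name) {
  nds <- networkNodes(spec)
  nds[[which(vapply(nds, `[[`, "", "name") == name)]]
}

test_that("the counting network realizes the reference layer plan", {
  spec <- buildCountNet(widthMultiplier = 1, inputSize = 128)
  # stem: 7x7 conv mapping the 3 RGB bands to 64 feature maps, stride 2
  stem <- nodeByName(spec, "stem1_conv")
  expect_identical(stem$kernel, c(7L, 7L))
  expect_identical(stem$outChannels, 64L)
  expect_identical(stem$stride, 2L)
  sh <- inferShapes(spec)
  expect_identical(sh[["input"]][3], 3L)
  expect_identical(sh[["stem1_conv"]][3], 64L)
  # final fully connected hidden layer is 768 wide
  expect_identical(nodeByName(spec, "head_fc1")$outChannels, 768L)
  # A-module linear projection calculates 192 features pre-reduction
  expect_identical(nodeByName(spec, "a1_proj_conv")$outChannels, 192L)
  expect_identical(nodeByName(spec, "a2_proj_conv")$outChannels, 192L)
  # head dropout keeps 65 percent
  expect_equal(nodeByName(spec, "head_dropout")$keep, 0.65)
  # scalar output
  expect_identical(sh[["head_out"]], c(1L, 1L, 1L))
})

test_that("a batchnorm immediately follows every convolution", {
  for (spec in list(buildCountNet(0.5, 64), buildShallowNet(64))) {
    nds <- networkNodes(spec)
    names(nds) <- vapply(nds, `[[`, "", "name")
    for (nd in nds) {
      if (nd$kind != "conv") next
      consumers <- Filter(function(x) nd$name %in% x$inputs, nds)
      expect_length(consumers, 1)
      expect_identical(consumers[[1]]$kind, "batchnorm")
    }
  }
})

test_that("A-module outputs match their inputs and the reduction widens by 256", {
  spec <- buildCountNet(widthMultiplier = 1, inputSize = 128)
  sh <- inferShapes(spec)
  for (m in c("a1", "a2", "a3", "a4")) {
    addNode <- nodeByName(spec, paste0(m, "_add"))
    shapesIn <- lapply(addNode$inputs, function(n) sh[[n]])
    expect_identical(shapesIn[[1]], shapesIn[[2]])
    expect_identical(sh[[paste0(m, "_relu")]],
                     sh[[addNode$inputs[1]]])
  }
  inRed <- sh[["a2_relu"]]
  outRed <- sh[["red_concat"]]
  expect_identical(outRed[3], inRed[3] + 256L)
  # stride-2 unpadded: spatial extent floor((s - 3) / 2) + 1
  expect_identical(outRed[1], (inRed[1] - 3L) %/% 2L + 1L)
})

test_that("shape inference agrees with hand arithmetic at 32, 64 and 128 px", {
  expected <- list(
    `32` = list(stem1_conv = c(16L, 16L, 64L), stem_pool = c(7L, 7L, 64L),
                a2_relu = c(7L, 7L, 192L), red_concat = c(3L, 3L, 448L),
                head_pool = c(1L, 1L, 448L), head_flatten = c(1L, 1L, 448L)),
    `64` = list(stem1_conv = c(32L, 32L, 64L), stem_pool = c(15L, 15L, 64L),
                a2_relu = c(15L, 15L, 192L), red_concat = c(7L, 7L, 448L),
                head_pool = c(3L, 3L, 448L),
                head_flatten = c(1L, 1L, 4032L)),
    `128` = list(stem1_conv = c(64L, 64L, 64L),
                 stem_pool = c(31L, 31L, 64L),
                 a2_relu = c(31L, 31L, 192L), red_concat = c(15L, 15L, 448L),
                 head_pool = c(7L, 7L, 448L),
                 head_flatten = c(1L, 1L, 21952L)))
  for (px in c(32, 64, 128)) {
    sh <- inferShapes(buildCountNet(1, px))
    for (node in names(expected[[as.character(px)]]))
      expect_identical(sh[[node]], expected[[as.character(px)]][[node]],
                       label = sprintf("%s at %d px", node, px))
  }
})

test_that("mismatched residual operands and undersized inputs are rejected", {
  gcns <- asNamespace("glanceCount")
  nodes <- list(
    list(name = "input", kind = "input"),
    gcns$nodeConv("c1", "input", 3, 4),
    gcns$nodeConv("c2", "input", 3, 6),
    gcns$nodeAdd("bad_add", "c1", "c2"))
  expect_error(networkSpec(nodes, 16), "bad_add")
  expect_error(buildCountNet(1, 16), "inputSize")
  expect_error(buildShallowNet(8), "inputSize")
})

test_that("parameter counting matches closed-form values and grows with width", {
  gcns <- asNamespace("glanceCount")
  # single bias-free 1x1 conv, 64 -> 32 channels: 1*1*64*32 = 2048 weights
  conv <- networkSpec(list(
    list(name = "input", kind = "input"),
    gcns$nodeConv("c", "input", 1, 32)), 8)
  convOnly <- countParameters(conv) -
    0  # conv weights only; no batchnorm present in this graph
  expect_identical(convOnly, 1 * 1 * 3 * 32)  # input has 3 channels
  conv64 <- networkSpec(list(
    list(name = "input", kind = "input"),
    gcns$nodeConv("widen", "input", 1, 64),
    gcns$nodeConv("c", "widen", 1, 32)), 8)
  expect_identical(countParameters(conv64) - countParameters(
    networkSpec(list(list(name = "input", kind = "input"),
                     gcns$nodeConv("widen", "input", 1, 64)), 8)),
    1 * 1 * 64 * 32)
  # fully connected 448 -> 768 with bias: 448*768 + 768 = 344832
  fcspec <- networkSpec(list(
    list(name = "input", kind = "input"),
    gcns$nodeConv("widen", "input", 1, 7),
    gcns$nodeFlatten("fl", "widen"),
    gcns$nodeFC("fc", "fl", 768)), 8)
  base <- networkSpec(list(
    list(name = "input", kind = "input"),
    gcns$nodeConv("widen", "input", 1, 7),
    gcns$nodeFlatten("fl", "widen")), 8)
  expect_identical(countParameters(fcspec) - countParameters(base),
                   448 * 768 + 768)
  # monotone in the width multiplier
  expect_lt(countParameters(buildCountNet(0.25, 32)),
            countParameters(buildCountNet(0.5, 32)))
  expect_lt(countParameters(buildCountNet(0.5, 32)),
            countParameters(buildCountNet(1, 32)))
})

test_that("the shallow baseline has exactly two conv and two fc layers", {
  spec <- buildShallowNet(32)
  kinds <- nodeKinds(spec)
  expect_identical(sum(kinds == "conv"), 2L)
  expect_identical(sum(kinds == "fc"), 2L)
  sh <- inferShapes(spec)
  expect_identical(sh[[length(sh)]], c(1L, 1L, 1L))
  params <- xavierInit(spec, seed = 2)
  imgs <- lapply(1:3, function(i)
    array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)))
  out <- forwardNetwork(spec, params, imgs)
  expect_length(out, 3)
  expect_true(all(is.finite(out)))
})

test_that("inference is deterministic and per-image independent", {
  spec <- buildCountNet(0.25, 32)
  params <- xavierInit(spec, seed = 11)
  set.seed(99)
  imgs <- lapply(1:4, function(i)
    array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)))
  o1 <- forwardNetwork(spec, params, imgs)
  o2 <- forwardNetwork(spec, params, imgs)
  expect_identical(o1, o2)
  expect_true(all(is.finite(o1)))
  perm <- c(3, 1, 4, 2)
  expect_equal(forwardNetwork(spec, params, imgs[perm]), o1[perm],
               tolerance = 1e-12)
})

test_that("architectures survive a JSON round trip", {
  spec <- buildCountNet(0.5, 64)
  js <- networkToJSON(spec)
  back <- networkFromJSON(js)
  expect_identical(length(networkNodes(back)), length(networkNodes(spec)))
  expect_identical(inferShapes(back), inferShapes(spec))
  expect_identical(countParameters(back), countParameters(spec))
  f <- tempfile(fileext = ".json")
  networkToJSON(spec, f)
  expect_identical(countParameters(networkFromJSON(f)),
                   countParameters(spec))
})
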