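# Synthetic tomato-scene generation with exact count labels.
#
# A scene is rendered in five stages: (1) the canvas is filled with green
# and brown blobs simulating background and plant, (2) the background layer
# is blurred with a Gaussian filter, (3) shaded circular fruit of random
# size are drawn at random positions with overlap arising from draw order,
# (4) foliage blobs are optionally painted over the fruit layer, and (5) a
# smooth multiplicative illumination field (plus per-fruit shadows applied
# at stage 3) modulates brightness.  An ownership map tracks which fruit
# each pixel belongs to, so every fruit's visible fraction is known exactly
# and placements that would sink a fruit below the visibility floor are
# retried -- the count label always equals the number of fruit drawn.

defaultPalette <- function() {
  rbind(
    c(34, 80, 34),    # dark leaf green
    c(60, 110, 45),   # mid green
    c(88, 128, 60),   # light green
    c(45, 95, 55),    # blue-green
    c(110, 85, 50),   # light brown (branches/soil)
    c(90, 70, 40),    # mid brown
    c(70, 55, 35))    # dark brown
}

#' Construct a scene-generator configuration
#'
#' Defaults reproduce the study conditions of the counting experiments:
#' 128 x 128 px scenes, 1 to 40 fruit per scene drawn uniformly, fruit radii
#' between 3 and 12 percent of the image side, a background of 40-80
#' green/brown blobs blurred with sigma 2, 30 percent illumination
#' amplitude, 25 percent per-fruit shadow probability, 20 percent foliage
#' occluder probability and a 25 percent visibility floor.
#'
#' @param imageSize pixels per side.
#' @param countRange inclusive integer range of fruit per scene.
#' @param radiusRange fruit radius range as a fraction of the image side.
#' @param ripenessMix probability a fruit is ripe (red) rather than
#'   half-ripe (orange).
#' @param blobCountRange number of background blobs.
#' @param palette n x 3 matrix of background base RGB colors.
#' @param paletteJitter per-channel uniform jitter added to base colors.
#' @param blurSigma Gaussian standard deviation (pixels) for the background
#'   layer.
#' @param fullBlurSigma optional light blur of the finished image (0 = off).
#' @param illumAmplitude amplitude of the multiplicative brightness field.
#' @param shadowProb per-fruit shadow probability.
#' @param occluderProb per-fruit foliage-occluder probability.
#' @param minVisibleFraction minimum unoccluded fraction per fruit.
#' @param seed generator seed.
#' @return a [SceneConfig-class].
#' @export
sceneConfig <- function(imageSize = 128, countRange = c(1, 40),
                        radiusRange = c(0.03, 0.12), ripenessMix = 0.7,
                        blobCountRange = c(40, 80),
                        palette = defaultPalette(), paletteJitter = 25,
                        blurSigma = 2, fullBlurSigma = 0,
                        illumAmplitude = 0.3, shadowProb = 0.25,
                        occluderProb = 0.2, minVisibleFraction = 0.25,
                        seed = 1) {
  obj <- new("SceneConfig", imageSize = as.integer(imageSize),
             countRange = as.integer(countRange),
             radiusRange = as.numeric(radiusRange),
             ripenessMix = ripenessMix,
             blobCountRange = as.integer(blobCountRange),
             palette = palette, paletteJitter = paletteJitter,
             blurSigma = blurSigma, fullBlurSigma = fullBlurSigma,
             illumAmplitude = illumAmplitude, shadowProb = shadowProb,
             occluderProb = occluderProb,
             minVisibleFraction = minVisibleFraction,
             seed = as.integer(seed))
  validObject(obj)
  obj
}

# Row/column indices and center distances of the disk (cx, cy, r) clipped
# to an H x H canvas.  Rows index y, columns index x.
diskPixels <- function(cx, cy, r, H) {
  x0 <- max(1L, as.integer(ceiling(cx - r)))
  x1 <- min(H, as.integer(floor(cx + r)))
  y0 <- max(1L, as.integer(ceiling(cy - r)))
  y1 <- min(H, as.integer(floor(cy + r)))
  if (x0 > x1 || y0 > y1)
    return(list(rows = integer(), cols = integer(), d = numeric()))
  xs <- x0:x1
  ys <- y0:y1
  g <- expand.grid(y = ys, x = xs)
  d <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  keep <- d <= r
  list(rows = g$y[keep], cols = g$x[keep], d = d[keep])
}

paintDisk <- function(img, px, rgb) {
  for (ch in 1:3) img[cbind(px$rows, px$cols, ch)] <- rgb[ch]
  img
}

gaussianBlurRGB <- function(img, sigma) {
  if (sigma <= 0) return(img)
  out <- EBImage::gblur(EBImage::Image(img / 255, colormode = "Color"),
                        sigma = sigma)
  EBImage::imageData(out) * 255
}

# Smooth multiplicative brightness field: bilinear surface over random
# corner offsets, amplitude-scaled.
illuminationField <- function(H, amplitude) {
  corners <- matrix(runif(4, -1, 1), 2, 2)
  u <- (seq_len(H) - 1) / (H - 1)
  field <- outer(u, u, function(y, x)
    corners[1, 1] * (1 - y) * (1 - x) + corners[1, 2] * (1 - y) * x +
    corners[2, 1] * y * (1 - x) + corners[2, 2] * y * x)
  1 + amplitude * field
}

#' Render one synthetic scene
#'
#' Stages run in a fixed order (background blobs, Gaussian blur, shaded
#' fruit disks, foliage occluders, illumination field), and the same
#' (config, seed) pair yields a byte-identical image.  The count label
#' equals the number of fruit disks drawn; a placement or occluder that
#' would leave any fruit with less than `minVisibleFraction` of its disk
#' visible is retried, so labels stay honest under occlusion.
#'
#' @param config a [SceneConfig-class].
#' @param seed per-scene RNG seed (defaults to the config seed).
#' @return a [LabeledScene-class].
#' @examples
#' sc <- renderScene(sceneConfig(imageSize = 32, countRange = c(2, 5)),
#'                   seed = 7)
#' fruitCount(sc)
#' @export
renderScene <- function(config, seed = config@seed) {
  validObject(config)
  H <- config@imageSize
  withSeed(seed, function() {
    ## stage 1: background blobs over a base tone
    base <- config@palette[1, ]
    img <- array(rep(base, each = H * H), c(H, H, 3))
    nBlob <- if (config@blobCountRange[1] == config@blobCountRange[2])
      config@blobCountRange[1] else
      sample(config@blobCountRange[1]:config@blobCountRange[2], 1)
    for (b in seq_len(nBlob)) {
      col <- config@palette[sample(nrow(config@palette), 1), ] +
        runif(3, -config@paletteJitter, config@paletteJitter)
      px <- diskPixels(runif(1, 1, H), runif(1, 1, H),
                       runif(1, 0.05, 0.28) * H, H)
      img <- paintDisk(img, px, pmin(255, pmax(0, col)))
    }

    ## stage 2: blur the background layer only
    img <- gaussianBlurRGB(img, config@blurSigma)

    ## stage 3: fruit geometry under the visibility floor
    count <- if (config@countRange[1] == config@countRange[2])
      config@countRange[1] else
      sample(config@countRange[1]:config@countRange[2], 1)
    own <- matrix(0L, H, H)
    fr <- vector("list", count)
    diskArea <- numeric(count)
    visOK <- function(ownMap, areas, k) {
      if (k == 0) return(TRUE)
      vis <- tabulate(ownMap[ownMap > 0L], nbins = k)
      all(vis / areas[seq_len(k)] >= config@minVisibleFraction)
    }
    i <- 0L
    while (i < count) {
      i <- i + 1L
      placed <- FALSE
      for (try in 1:200) {
        r <- if (try <= 30)
          runif(1, config@radiusRange[1], config@radiusRange[2]) * H
        else config@radiusRange[1] * H
        cx <- runif(1, 1, H); cy <- runif(1, 1, H)
        px <- diskPixels(cx, cy, r, H)
        if (length(px$rows) < 1) next
        cand <- own
        cand[cbind(px$rows, px$cols)] <- i
        diskArea[i] <- length(px$rows)
        if (visOK(cand, diskArea, i)) {
          own <- cand
          fr[[i]] <- list(x = cx, y = cy, radius = r)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place all fruit above the visibility floor; the scene is over-crowded for minVisibleFraction")
    }

    ## stage 3b: render fruit in draw order (ownership = occlusion order)
    fruits <- data.frame(
      x = vapply(fr, `[[`, 0, "x"), y = vapply(fr, `[[`, 0, "y"),
      radius = vapply(fr, `[[`, 0, "radius"),
      ripeness = character(count), visibleFraction = numeric(count),
      stringsAsFactors = FALSE)
    if (count == 0)
      fruits <- data.frame(x = numeric(), y = numeric(), radius = numeric(),
                           ripeness = character(),
                           visibleFraction = numeric())
    for (i in seq_len(count)) {
      ripe <- runif(1) < config@ripenessMix
      fruits$ripeness[i] <- if (ripe) "ripe" else "half_ripe"
      baseCol <- if (ripe)
        c(200 + runif(1, -25, 25), 25 + runif(1, -15, 25),
          25 + runif(1, -15, 20))
      else
        c(235 + runif(1, -20, 15), 140 + runif(1, -25, 25),
          35 + runif(1, -15, 20))
      shadow <- if (runif(1) < config@shadowProb) runif(1, 0.45, 0.7) else 1
      f <- fr[[i]]
      px <- diskPixels(f$x, f$y, f$radius, H)
      sel <- own[cbind(px$rows, px$cols)] == i
      if (!any(sel)) next
      rows <- px$rows[sel]; cols <- px$cols[sel]; d <- px$d[sel]
      # radial shading: bright sphere-like center, darker rim
      shade <- 0.55 + 0.45 * sqrt(pmax(0, 1 - (d / f$radius)^2))
      # specular highlight offset toward the upper-left light
      hx <- f$x - 0.35 * f$radius; hy <- f$y - 0.35 * f$radius
      dh <- sqrt((cols - hx)^2 + (rows - hy)^2)
      hl <- 0.55 * exp(-(dh / (0.4 * f$radius))^2)
      for (ch in 1:3) {
        v <- baseCol[ch] * shade
        v <- (v + (255 - v) * hl) * shadow
        img[cbind(rows, cols, ch)] <- pmin(255, pmax(0, v))
      }
    }

    ## stage 4: foliage occluders over the fruit layer
    for (i in seq_len(count)) {
      if (runif(1) >= config@occluderProb) next
      f <- fr[[i]]
      for (attempt in 1:2) {
        orad <- runif(1, 0.5, 1.1) * f$radius / attempt
        ocx <- f$x + runif(1, -1, 1) * f$radius
        ocy <- f$y + runif(1, -1, 1) * f$radius
        px <- diskPixels(ocx, ocy, orad, H)
        if (length(px$rows) < 1) break
        cand <- own
        cand[cbind(px$rows, px$cols)] <- -1L
        if (visOK(cand, diskArea, count)) {
          own <- cand
          col <- pmin(255, pmax(0, c(50, 100, 40) + runif(3, -20, 20)))
          img <- paintDisk(img, px, col)
          break
        }
      }
    }
    # repaint foliage only where it actually owns pixels is implicit: a
    # rejected occluder was never painted, an accepted one may also cover
    # background, which is visually equivalent to a foliage blob there.

    if (count > 0) {
      vis <- tabulate(own[own > 0L], nbins = count)
      fruits$visibleFraction <- vis / diskArea
    }

    ## stage 5: illumination field, optional camera softness, quantize
    if (config@illumAmplitude > 0) {
      field <- illuminationField(H, config@illumAmplitude)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * field
    }
    if (config@fullBlurSigma > 0)
      img <- gaussianBlurRGB(img, config@fullBlurSigma)
    pix <- array(as.integer(pmin(255, pmax(0, round(img)))), c(H, H, 3))

    new("LabeledScene", pixels = pix, count = as.integer(count),
        fruits = fruits, seed = as.integer(seed))
  })
}

sceneConfigToList <- function(config) {
  list(imageSize = config@imageSize, countRange = config@countRange,
       radiusRange = config@radiusRange, ripenessMix = config@ripenessMix,
       blobCountRange = config@blobCountRange,
       palette = apply(config@palette, 1, function(r) as.numeric(r),
                       simplify = FALSE),
       paletteJitter = config@paletteJitter, blurSigma = config@blurSigma,
       fullBlurSigma = config@fullBlurSigma,
       illumAmplitude = config@illumAmplitude,
       shadowProb = config@shadowProb, occluderProb = config@occluderProb,
       minVisibleFraction = config@minVisibleFraction, seed = config@seed)
}

sceneConfigFromList <- function(x) {
  sceneConfig(imageSize = x$imageSize, countRange = unlist(x$countRange),
              radiusRange = unlist(x$radiusRange),
              ripenessMix = x$ripenessMix,
              blobCountRange = unlist(x$blobCountRange),
              palette = do.call(rbind, lapply(x$palette, unlist)),
              paletteJitter = x$paletteJitter, blurSigma = x$blurSigma,
              fullBlurSigma = x$fullBlurSigma,
              illumAmplitude = x$illumAmplitude, shadowProb = x$shadowProb,
              occluderProb = x$occluderProb,
              minVisibleFraction = x$minVisibleFraction, seed = x$seed)
}

#' Generate a labeled image dataset
#'
#' Renders `n` scenes to 8-bit RGB PNG files plus a `path,count` CSV
#' manifest and a sidecar JSON holding the configuration snapshot, split
#' name and master seed.  Per-image seeds are derived deterministically from
#' the master seed and the image index, so datasets are order-independent,
#' resumable and byte-reproducible.
#'
#' @param config a [SceneConfig-class].
#' @param n number of images.
#' @param splitName split label, e.g. `"train"` or `"test"`.
#' @param outDir output directory (created if missing).
#' @param seed master seed (defaults to the config seed).
#' @param progress print a dot every 500 images.
#' @return a [DatasetManifest-class].
#' @export
generateDataset <- function(config, n, splitName, outDir,
                            seed = config@seed, progress = FALSE) {
  validObject(config)
  stopifnot(n >= 0)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop(sprintf("cannot create '%s'", outDir))
  paths <- character(n); counts <- integer(n)
  for (i in seq_len(n)) {
    sc <- renderScene(config, seed = deriveSeed(seed, i))
    fname <- sprintf("%s_%06d.png", splitName, i)
    png::writePNG(scenePixels(sc) / 255,
                  target = file.path(outDir, fname))
    paths[i] <- fname; counts[i] <- fruitCount(sc)
    if (progress && i %% 500 == 0) cat(".")
  }
  entries <- data.frame(path = paths, count = counts,
                        stringsAsFactors = FALSE)
  write.csv(entries, file.path(outDir, paste0(splitName, "_manifest.csv")),
            row.names = FALSE)
  jsonlite::write_json(
    list(splitName = splitName, seed = as.integer(seed), n = n,
         config = sceneConfigToList(config)),
    file.path(outDir, paste0(splitName, "_manifest.json")),
    auto_unbox = TRUE, digits = NA)
  entries$path <- file.path(outDir, entries$path)
  new("DatasetManifest", splitName = splitName, entries = entries,
      config = config, seed = as.integer(seed))
}

#' Reload a dataset manifest written by [generateDataset()]
#'
#' @param outDir dataset directory.
#' @param splitName split label used at generation time.
#' @return a [DatasetManifest-class].
#' @export
readManifest <- function(outDir, splitName) {
  csv <- file.path(outDir, paste0(splitName, "_manifest.csv"))
  js <- file.path(outDir, paste0(splitName, "_manifest.json"))
  if (!file.exists(csv)) stop(sprintf("no manifest at '%s'", csv))
  entries <- read.csv(csv, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(js)
  entries$path <- file.path(outDir, entries$path)
  new("DatasetManifest", splitName = splitName, entries = entries,
      config = sceneConfigFromList(meta$config),
      seed = as.integer(meta$seed))
}

#' Load the images and labels of a dataset
#'
#' @param manifest a [DatasetManifest-class].
#' @return list with one element per image, each
#'   `list(image = <H x W x 3 integer array>, count = <integer>,
#'   path = <file>)`, in manifest order.
#' @export
loadDataset <- function(manifest) {
  entries <- manifestEntries(manifest)
  lapply(seq_len(nrow(entries)), function(i) {
    p <- entries$path[i]
    if (!file.exists(p))
      stop(sprintf("dataset image missing: '%s'", p))
    img <- png::readPNG(p)
    list(image = array(as.integer(round(img * 255)), dim(img)),
         count = entries$count[i], path = p)
  })
}
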