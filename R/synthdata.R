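# Synthetic hierarchical image benchmark.
#
# Images are procedural: visual attributes are assigned per taxonomy node
# from fixed palettes and shape alphabets indexed by category id, so
# categories grouped under the same node share common features and the
# visual signal is rank-nested — the coarsest rank controls the background
# hue (most pixels), intermediate ranks control the subject silhouette,
# fill texture and stroke, and the finest rank controls only a small
# leaf-specific marking. Degradations emulate field imagery: variable
# subject scale and position, background clutter, additive Gaussian noise,
# and occasional blur.

#' Specification of a synthetic hierarchical image dataset
#'
#' @param branching integer vector: children per parent at each level, so the
#'   level sizes are the cumulative products of `branching`.
#' @param samplesPerLeaf scalar, or one count per leaf for class imbalance.
#' @param imageSize square image side in pixels.
#' @param subjectScaleRange fraction of the frame covered by the subject's
#'   bounding box, drawn uniformly per sample; a wide range reproduces the
#'   "subject covers the whole frame vs. a small patch" pathology.
#' @param noiseSigma additive Gaussian pixel noise standard deviation.
#' @param blurProb probability that a sample is blurred (sigma 1 px).
#' @param clutter number of low-contrast background rectangles.
#' @param seed master seed; all per-sample streams are derived from it by
#'   counter-based splitting, so generation order never changes content.
#' @return a list with class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(branching, samplesPerLeaf = 20L, imageSize = 32L,
                          subjectScaleRange = c(0.3, 0.95), noiseSigma = 0.05,
                          blurProb = 0.25, clutter = 3L, seed = 1L) {
  branching <- as.integer(branching)
  if (length(branching) == 0L || any(branching < 1L))
    stopf("branching must be positive integers")
  if (subjectScaleRange[1L] <= 0 || subjectScaleRange[2L] > 1 ||
      subjectScaleRange[1L] > subjectScaleRange[2L])
    stopf("subjectScaleRange must be within (0, 1]")
  if (noiseSigma < 0) stopf("noiseSigma must be >= 0")
  nLeaf <- prod(branching)
  if (length(samplesPerLeaf) == 1L) samplesPerLeaf <- rep(samplesPerLeaf, nLeaf)
  if (length(samplesPerLeaf) != nLeaf)
    stopf("samplesPerLeaf must have length 1 or %d", nLeaf)
  structure(list(branching = branching,
                 samplesPerLeaf = as.integer(samplesPerLeaf),
                 imageSize = as.integer(imageSize),
                 subjectScaleRange = subjectScaleRange,
                 noiseSigma = noiseSigma, blurProb = blurProb,
                 clutter = as.integer(clutter), seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Synthetic taxonomy with uniform branching
#'
#' Level `i` has `prod(branching[1:i])` categories; node `j` (0-based) at
#' level `i` has parent `j %/% branching[i]`. Display names are zero-padded
#' so lexicographic id assignment coincides with numeric order.
#'
#' @param branching children per parent at each level.
#' @param levelNames optional level names.
#' @return a [TaxonomyTree-class].
#' @export
makeSyntheticTaxonomy <- function(branching,
                                  levelNames = paste0("level", seq_along(branching) - 1L)) {
  sizes <- cumprod(as.integer(branching))
  L <- length(sizes)
  nms <- vector("list", L)
  parent <- vector("list", L)
  parent[[1L]] <- integer(0)
  for (i in seq_len(L)) {
    nms[[i]] <- paste0("L", i - 1L, "_", padId(seq_len(sizes[i]) - 1L, sizes[i]))
    if (i > 1L) parent[[i]] <- (seq_len(sizes[i]) - 1L) %/% as.integer(branching[i])
  }
  new("TaxonomyTree", levelNames = as.character(levelNames),
      names = nms, parent = parent)
}

#' Synthetic taxonomy with prescribed level sizes
#'
#' Builds a valid tree whose levels have exactly the requested sizes (sizes
#' must be non-decreasing, coarsest first); child `j` at level `i` nests
#' under parent `floor(j * size[i-1] / size[i])`. Useful for reproducing the
#' shape of a real taxonomy (e.g. 3/4/9/34/57/72/1010) without its data.
#'
#' @param sizes non-decreasing integer vector of category counts per level.
#' @param levelNames optional level names.
#' @return a [TaxonomyTree-class].
#' @export
makeShapedTaxonomy <- function(sizes,
                               levelNames = paste0("level", seq_along(sizes) - 1L)) {
  sizes <- as.integer(sizes)
  if (any(diff(sizes) < 0L)) stopf("level sizes must be non-decreasing")
  L <- length(sizes)
  nms <- vector("list", L)
  parent <- vector("list", L)
  parent[[1L]] <- integer(0)
  for (i in seq_len(L)) {
    nms[[i]] <- paste0("N", i - 1L, "_", padId(seq_len(sizes[i]) - 1L, sizes[i]))
    if (i > 1L) {
      j <- seq_len(sizes[i]) - 1L
      parent[[i]] <- as.integer(floor(j * sizes[i - 1L] / sizes[i]))
    }
  }
  new("TaxonomyTree", levelNames = as.character(levelNames),
      names = nms, parent = parent)
}

hsvCol <- function(h, s, v) as.numeric(grDevices::col2rgb(grDevices::hsv(h %% 1, s, v))) / 255

shapeAlphabet <- c("disc", "square", "triangle", "diamond", "ring", "cross",
                   "hbar", "vbar")

shapeMask <- function(shape, side) {
  g <- (seq_len(side) - 0.5) / side
  rx <- matrix(g, side, side, byrow = TRUE)
  ry <- matrix(g, side, side)
  switch(shape,
    disc = (rx - 0.5)^2 + (ry - 0.5)^2 <= 0.25,
    square = matrix(TRUE, side, side),
    triangle = ry >= 2 * abs(rx - 0.5),
    diamond = abs(rx - 0.5) + abs(ry - 0.5) <= 0.5,
    ring = ((rx - 0.5)^2 + (ry - 0.5)^2 <= 0.25) &
           ((rx - 0.5)^2 + (ry - 0.5)^2 >= 0.08),
    cross = abs(rx - 0.5) <= 0.17 | abs(ry - 0.5) <= 0.17,
    hbar = abs(ry - 0.5) <= 0.22,
    vbar = abs(rx - 0.5) <= 0.22)
}

# roles of the levels between root hue and leaf marking
midRoles <- c("shape", "texture", "stroke")

#' Render one synthetic sample
#'
#' Deterministic given `seed`: two calls with the same seed produce identical
#' tensors, and two leaves sharing all ancestors except the finest level
#' differ only inside the leaf-marking region (geometry draws do not depend
#' on the leaf identity).
#'
#' @param tree a [TaxonomyTree-class] (from [makeSyntheticTaxonomy()]).
#' @param leafId 0-based finest-level category id.
#' @param spec a [syntheticSpec()].
#' @param seed per-sample seed.
#' @return `imageSize x imageSize x 3` array in `[0,1]`.
#' @export
renderSample <- function(tree, leafId, spec, seed = spec$seed) {
  path <- ancestorPath(tree, leafId)
  L <- nLevels(tree)
  size <- spec$imageSize
  # per-level visual attributes
  bgId <- path[1L]
  bg <- hsvCol(0.07 + bgId * 0.37, 0.45, 0.85)
  shape <- "disc"; texture <- "solid"; stroke <- 0L
  fill <- c(0.25, 0.25, 0.3)
  if (L > 2L) for (i in 2:(L - 1L)) {
    role <- midRoles[((i - 2L) %% length(midRoles)) + 1L]
    id <- path[i]
    if (role == "shape") {
      shape <- shapeAlphabet[(id %% length(shapeAlphabet)) + 1L]
      fill <- hsvCol(0.12 + id * 0.41, 0.9, 0.7)
    } else if (role == "texture") {
      texture <- c("solid", "hstripes", "vstripes", "checker")[(id %% 4L) + 1L]
    } else stroke <- (id %% 3L)
  }
  markId <- path[L]
  mark <- hsvCol(0.05 + markId * 0.618034, 1, 1)
  markAlt <- (markId %% 2L) == 1L # alternate marking value for neighbours
  if (markAlt) mark <- mark * 0.55 + 0.45

  withSeed(seed, {
    img <- array(rep(bg, each = size * size), c(size, size, 3L))
    # background clutter: low-contrast rectangles
    for (k in seq_len(spec$clutter)) {
      w <- sample(max(2L, size %/% 6L):max(3L, size %/% 3L), 2L, replace = TRUE)
      y <- sample.int(max(1L, size - w[1L]), 1L)
      x <- sample.int(max(1L, size - w[2L]), 1L)
      dv <- stats::runif(1L, -0.12, 0.12)
      img[y:(y + w[1L] - 1L), x:(x + w[2L] - 1L), ] <-
        clip01(img[y:(y + w[1L] - 1L), x:(x + w[2L] - 1L), , drop = FALSE] + dv)
    }
    # subject geometry
    sc <- stats::runif(1L, spec$subjectScaleRange[1L], spec$subjectScaleRange[2L])
    side <- max(4L, min(size, round(sc * size)))
    y0 <- sample.int(size - side + 1L, 1L)
    x0 <- sample.int(size - side + 1L, 1L)
    m <- shapeMask(shape, side)
    # fill with texture
    rows <- matrix(seq_len(side), side, side)
    cols <- t(rows)
    texmul <- switch(texture,
      solid = matrix(1, side, side),
      hstripes = ifelse(rows %% 4L < 2L, 1, 0.55),
      vstripes = ifelse(cols %% 4L < 2L, 1, 0.55),
      checker = ifelse(((rows - 1L) %/% 3L + (cols - 1L) %/% 3L) %% 2L == 0L, 1, 0.55))
    sub <- img[y0:(y0 + side - 1L), x0:(x0 + side - 1L), , drop = FALSE]
    for (ch in 1:3) {
      layer <- sub[, , ch]
      layer[m] <- (fill[ch] * texmul)[m]
      sub[, , ch] <- layer
    }
    # stroke: border band of the silhouette
    if (stroke > 0L) {
      band <- m & !(rows > 2L & rows < side - 1L & cols > 2L & cols < side - 1L)
      sval <- if (stroke == 1L) 0.05 else 0.95
      for (ch in 1:3) {
        layer <- sub[, , ch]
        layer[band] <- sval
        sub[, , ch] <- layer
      }
    }
    # leaf marking: small square patch at a fixed relative position
    ms <- max(2L, round(0.35 * side))
    my <- max(1L, round(0.5 * side) - ms %/% 2L)
    mx <- max(1L, round(0.5 * side) - ms %/% 2L)
    for (ch in 1:3)
      sub[my:(my + ms - 1L), mx:(mx + ms - 1L), ch] <- mark[ch]
    img[y0:(y0 + side - 1L), x0:(x0 + side - 1L), ] <- sub
    # degradations
    if (spec$noiseSigma > 0)
      img <- img + array(stats::rnorm(length(img), sd = spec$noiseSigma), dim(img))
    if (spec$blurProb > 0 && stats::runif(1L) < spec$blurProb)
      img <- gaussianBlurImage(img, 1)
    clip01(img)
  })
}

#' Bounding box of the leaf marking for a given sample seed
#'
#' Replays the geometry draws of [renderSample()] (which do not depend on the
#' leaf identity) and returns the marking region, for diagnostics and tests.
#'
#' @param spec a [syntheticSpec()].
#' @param seed the per-sample seed passed to [renderSample()].
#' @return named integer vector `y0, y1, x0, x1` (1-based, inclusive).
#' @export
markingBox <- function(spec, seed) {
  size <- spec$imageSize
  withSeed(seed, {
    for (k in seq_len(spec$clutter)) {
      w <- sample(max(2L, size %/% 6L):max(3L, size %/% 3L), 2L, replace = TRUE)
      sample.int(max(1L, size - w[1L]), 1L)
      sample.int(max(1L, size - w[2L]), 1L)
      stats::runif(1L)
    }
    sc <- stats::runif(1L, spec$subjectScaleRange[1L], spec$subjectScaleRange[2L])
    side <- max(4L, min(size, round(sc * size)))
    y0 <- sample.int(size - side + 1L, 1L)
    x0 <- sample.int(size - side + 1L, 1L)
    ms <- max(2L, round(0.35 * side))
    my <- max(1L, round(0.5 * side) - ms %/% 2L)
    mx <- max(1L, round(0.5 * side) - ms %/% 2L)
    c(y0 = y0 + my - 1L, y1 = y0 + my + ms - 2L,
      x0 = x0 + mx - 1L, x1 = x0 + mx + ms - 2L)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Renders every sample, writes PNGs under `outDir/images/`, a manifest CSV
#' and a taxonomy JSON, and returns the manifest. Per-leaf counts follow the
#' spec (imbalance honoured) and the train/test split is stratified by leaf.
#' The same spec and seed always produce byte-identical output.
#'
#' @param spec a [syntheticSpec()].
#' @param trainFraction fraction of each leaf's samples tagged "train".
#' @param outDir output directory (created if needed).
#' @param levelNames optional taxonomy level names.
#' @return a [DatasetManifest-class] rooted at `outDir`.
#' @export
generateDataset <- function(spec, trainFraction = 0.8, outDir,
                            levelNames = paste0("level", seq_along(spec$branching) - 1L)) {
  tree <- makeSyntheticTaxonomy(spec$branching, levelNames)
  L <- nLevels(tree)
  nLeaf <- levelSizes(tree)[L]
  dir.create(file.path(outDir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (leaf in seq_len(nLeaf) - 1L) {
    n <- spec$samplesPerLeaf[leaf + 1L]
    if (n == 0L) next
    nTrain <- round(n * trainFraction)
    ord <- withSeed(deriveSeed(spec$seed, 555L, leaf), sample.int(n))
    splitTag <- rep("test", n)
    splitTag[ord[seq_len(nTrain)]] <- "train"
    path <- ancestorPath(tree, leaf)
    for (k in seq_len(n)) {
      sd <- deriveSeed(spec$seed, leaf, k)
      img <- renderSample(tree, leaf, spec, sd)
      rel <- file.path("images", sprintf("leaf%s_%03d.png", padId(leaf, nLeaf), k))
      png::writePNG(img, file.path(outDir, rel))
      row <- data.frame(path = rel, split = splitTag[k], stringsAsFactors = FALSE)
      for (i in seq_len(L)) row[[paste0("label_level", i - 1L)]] <- path[i]
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- do.call(rbind, rows)
  manifest <- DatasetManifest(df, tree, outDir)
  writeManifestCSV(manifest, file.path(outDir, "manifest.csv"))
  taxonomyToJSON(tree, file.path(outDir, "taxonomy.json"))
  manifest
}
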