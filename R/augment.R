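#' Augmentation policy
#'
#' Bundles the augmentation regime and the parameter ranges of the six
#' standard operators. The regimes are:
#' \describe{
#'   \item{none}{no augmentation.}
#'   \item{standard}{random combination of horizontal/vertical flips, colour
#'     channel shifting, brightness and contrast alteration, additive Gaussian
#'     noise, and Gaussian blur, each with random parameters.}
#'   \item{central_crop}{a centred crop covering `cropFraction` of each linear
#'     dimension, taken from the original-resolution image before resizing;
#'     the standard operators are applied on top.}
#'   \item{multiscale_crop}{three centred crops with side fractions drawn
#'     uniformly from `multiscaleRange`; the standard operators are applied on
#'     top.}
#' }
#' The operator parameter ranges default to mild perturbations; all are
#' recorded in the policy so a run's augmentation is fully auditable.
#'
#' @param mode one of "none", "standard", "central_crop", "multiscale_crop".
#' @param seed integer seed from which per-record transform seeds are derived.
#' @param pFlipH,pFlipV,pShift,pBrightness,pContrast,pNoise,pBlur inclusion
#'   probability of each operator.
#' @param shiftMax maximum per-channel shift (uniform in `[-shiftMax, shiftMax]`).
#' @param brightnessRange additive brightness delta range.
#' @param contrastRange multiplicative contrast factor range.
#' @param noiseSdRange Gaussian noise standard-deviation range.
#' @param blurSigmaRange Gaussian blur sigma range, pixels.
#' @param cropFraction central-crop side fraction.
#' @param multiscaleRange side-fraction range for multiscale crops.
#' @return a list with class `"AugmentPolicy"`.
#' @export
augmentPolicy <- function(mode = c("standard", "none", "central_crop", "multiscale_crop"),
                          seed = 1L,
                          pFlipH = 0.5, pFlipV = 0.5, pShift = 0.5,
                          pBrightness = 0.5, pContrast = 0.5,
                          pNoise = 0.5, pBlur = 0.5,
                          shiftMax = 0.1,
                          brightnessRange = c(-0.2, 0.2),
                          contrastRange = c(0.8, 1.2),
                          noiseSdRange = c(0, 0.05),
                          blurSigmaRange = c(0, 1.5),
                          cropFraction = 0.8,
                          multiscaleRange = c(0.5, 0.8)) {
  mode <- match.arg(mode)
  structure(list(mode = mode, seed = as.integer(seed),
                 pFlipH = pFlipH, pFlipV = pFlipV, pShift = pShift,
                 pBrightness = pBrightness, pContrast = pContrast,
                 pNoise = pNoise, pBlur = pBlur,
                 shiftMax = shiftMax, brightnessRange = brightnessRange,
                 contrastRange = contrastRange, noiseSdRange = noiseSdRange,
                 blurSigmaRange = blurSigmaRange, cropFraction = cropFraction,
                 multiscaleRange = multiscaleRange),
            class = "AugmentPolicy")
}

#' Separable Gaussian blur
#'
#' Edge pixels are replicated; `sigma = 0` is the identity.
#'
#' @param img H x W x C array.
#' @param sigma blur standard deviation in pixels.
#' @return blurred array of the same shape.
#' @export
gaussianBlurImage <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(img)
  img <- array(img, c(d[1L], d[2L], if (length(d) >= 3L) d[3L] else 1L))
  blur1d <- function(m) { # along rows of a matrix
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-r, r), "+")
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2L * r + 1L)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  out <- img
  for (ch in seq_len(dim(img)[3L])) {
    m <- blur1d(img[, , ch])
    out[, , ch] <- t(blur1d(t(m)))
  }
  out
}

#' Apply the standard augmentation operators
#'
#' A random subset (at least one) of the enabled operators is applied in a
#' fixed canonical order — flips, channel shift, brightness, contrast, noise,
#' blur — each with parameters drawn from the policy ranges. Output is
#' clipped to `[0,1]` and has the input shape.
#'
#' @param image H x W x 3 array in `[0,1]`.
#' @param policy an [augmentPolicy()].
#' @param seed integer seed; the same seed reproduces the same transform.
#' @return augmented array.
#' @export
standardAugment <- function(image, policy = augmentPolicy(), seed = policy$seed) {
  withSeed(seed, {
    probs <- c(flipH = policy$pFlipH, flipV = policy$pFlipV,
               shift = policy$pShift, brightness = policy$pBrightness,
               contrast = policy$pContrast, noise = policy$pNoise,
               blur = policy$pBlur)
    on <- stats::runif(7L) < probs
    if (!any(on)) {
      enabled <- which(probs > 0)
      if (length(enabled)) on[enabled[sample.int(length(enabled), 1L)]] <- TRUE
    }
    x <- image
    if (on["flipH"]) x <- x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
    if (on["flipV"]) x <- x[rev(seq_len(dim(x)[1L])), , , drop = FALSE]
    if (on["shift"]) {
      d <- stats::runif(3L, -policy$shiftMax, policy$shiftMax)
      for (ch in 1:3) x[, , ch] <- x[, , ch] + d[ch]
    }
    if (on["brightness"])
      x <- x + stats::runif(1L, policy$brightnessRange[1L], policy$brightnessRange[2L])
    if (on["contrast"]) {
      f <- stats::runif(1L, policy$contrastRange[1L], policy$contrastRange[2L])
      x <- (x - 0.5) * f + 0.5
    }
    if (on["noise"]) {
      sd <- stats::runif(1L, policy$noiseSdRange[1L], policy$noiseSdRange[2L])
      if (sd > 0) x <- x + array(stats::rnorm(length(x), sd = sd), dim(x))
    }
    if (on["blur"])
      x <- gaussianBlurImage(x, stats::runif(1L, policy$blurSigmaRange[1L],
                                             policy$blurSigmaRange[2L]))
    clip01(x)
  })
}

#' Centred crop of an image
#'
#' The window side is `round(fraction * side)` per dimension with offset
#' `floor((1 - fraction) * side / 2)`; the crop is taken at the original
#' resolution, before any resize.
#'
#' @param image H x W x C array.
#' @param fraction side fraction in `(0, 1]`; 1 is the identity.
#' @return cropped array.
#' @export
centralCrop <- function(image, fraction) {
  d <- dim(image)
  H <- d[1L]; W <- d[2L]
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stopf("crop fraction must be in (0, 1], got %s", fraction)
  h <- round(fraction * H); w <- round(fraction * W)
  if (h < 1 || w < 1)
    stopf("crop fraction %s yields a zero-size window on a %dx%d image",
          fraction, H, W)
  # small epsilon guards against FP representation of (1 - fraction)
  oy <- floor((1 - fraction) * H / 2 + 1e-9)
  ox <- floor((1 - fraction) * W / 2 + 1e-9)
  image[(oy + 1):(oy + h), (ox + 1):(ox + w), , drop = FALSE]
}

#' Three centred crops at random scales
#'
#' Each crop's side fraction is drawn independently and uniformly from the
#' policy's `multiscaleRange` (default 50% to 80% of the original side).
#'
#' @param image H x W x C array.
#' @param seed integer seed.
#' @param range side-fraction range.
#' @return list of 3 cropped arrays.
#' @export
multiscaleCrops <- function(image, seed = 1L, range = c(0.5, 0.8)) {
  fr <- withSeed(seed, stats::runif(3L, range[1L], range[2L]))
  lapply(fr, function(f) centralCrop(image, f))
}

# Replay a stored (transform, seed) pair on a source image. Crops come before
# the standard operators; the resize to model resolution happens afterwards in
# loadImage.
replayTransform <- function(img, transform, seed, policy = NULL) {
  if (is.null(policy)) policy <- augmentPolicy(mode = "standard")
  if (transform == "central_crop") {
    img <- centralCrop(img, policy$cropFraction)
  } else if (transform == "multiscale_crop") {
    f <- withSeed(deriveSeed(seed, 7L),
                  stats::runif(1L, policy$multiscaleRange[1L], policy$multiscaleRange[2L]))
    img <- centralCrop(img, f)
  } else if (transform != "standard") {
    stopf("unknown transform '%s'", transform)
  }
  standardAugment(img, policy, seed)
}

#' Balance a training split to the most represented category
#'
#' Augmented copies of under-represented finest-level classes are added until
#' every class count equals the pre-balance maximum, so the balanced training
#' split has `n_classes * max_count` records. For the crop regimes, crop
#' records are added first (one per source for `central_crop`, three per
#' source for `multiscale_crop`) and the equalisation runs on the resulting
#' counts. Augmented images are not materialised: each new record stores its
#' source path, transform name and transform seed, and is rendered lazily by
#' [loadImage()]. Original records and the test split are never modified.
#'
#' @param manifest a [DatasetManifest-class] with a non-empty train split.
#' @param policy an [augmentPolicy()]; mode "none" returns the manifest
#'   unchanged.
#' @return the balanced [DatasetManifest-class].
#' @export
balanceDataset <- function(manifest, policy = augmentPolicy()) {
  if (policy$mode == "none") return(manifest)
  df <- manifest@records
  L <- nLevels(manifest)
  labCol <- paste0("label_level", L - 1L)
  train <- df[df$split == "train", , drop = FALSE]
  if (nrow(train) == 0L) stopf("balanceDataset: empty train split")
  isOrig <- is.na(train$transform)
  added <- list()
  if (policy$mode %in% c("central_crop", "multiscale_crop")) {
    nCrop <- if (policy$mode == "central_crop") 1L else 3L
    tf <- policy$mode
    src <- train[isOrig, , drop = FALSE]
    for (k in seq_len(nCrop)) {
      cp <- src
      cp$source_path <- src$path
      cp$transform <- tf
      cp$transform_seed <- vapply(seq_len(nrow(src)),
                                  function(i) deriveSeed(policy$seed, 1000L + k, i), 1L)
      added[[length(added) + 1L]] <- cp
    }
  }
  pool <- do.call(rbind, c(list(train), added))
  counts <- tabulate(pool[[labCol]] + 1L, nbins = levelSizes(manifest)[L])
  mx <- max(counts)
  for (cls in which(counts > 0L & counts < mx) - 1L) {
    srcRows <- train[isOrig & train[[labCol]] == cls, , drop = FALSE]
    if (nrow(srcRows) == 0L)
      srcRows <- train[train[[labCol]] == cls, , drop = FALSE]
    need <- mx - counts[cls + 1L]
    idx <- rep(seq_len(nrow(srcRows)), length.out = need)
    cp <- srcRows[idx, , drop = FALSE]
    cp$source_path <- ifelse(is.na(cp$source_path), cp$path, cp$source_path)
    cp$transform <- "standard"
    cp$transform_seed <- vapply(seq_len(need),
                                function(i) deriveSeed(policy$seed, cls, i), 1L)
    added[[length(added) + 1L]] <- cp
  }
  out <- do.call(rbind, c(list(df), added))
  DatasetManifest(out, manifest@tree, manifest@imageRoot)
}
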