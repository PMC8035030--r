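# Small convolutional feature extractor used as the default backbone.
#
# Full-scale architectures (ResNet50, InceptionV3, DenseNet201,
# EfficientNetB5, ...) plug in behind the same Backbone contract; the package
# itself ships a compact fixed-filter network so the whole stack runs on a
# CPU in seconds: three 3x3 convolution + ReLU + 2x2 average-pool blocks with
# seeded random (He-scaled) filters, followed by global average pooling.
# The classification heads on top of it are the trainable part.

conv2dSame <- function(x, W, b) {
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]; Ci <- d[3L]; Co <- dim(W)[4L]
  xp <- array(0, c(H + 2L, Wd + 2L, Ci))
  xp[2:(H + 1L), 2:(Wd + 1L), ] <- x
  out <- matrix(rep(b, each = H * Wd), H * Wd, Co)
  for (dh in 0:2) for (dw in 0:2) {
    sub <- xp[(1L + dh):(H + dh), (1L + dw):(Wd + dw), , drop = FALSE]
    dim(sub) <- c(H * Wd, Ci)
    out <- out + sub %*% matrix(W[dh + 1L, dw + 1L, , ], Ci, Co)
  }
  array(out, c(H, Wd, Co))
}

avgPool2 <- function(x) {
  d <- dim(x)
  H <- d[1L] - d[1L] %% 2L
  W <- d[2L] - d[2L] %% 2L
  x <- x[seq_len(H), seq_len(W), , drop = FALSE]
  (x[seq(1L, H, 2L), seq(1L, W, 2L), , drop = FALSE] +
   x[seq(2L, H, 2L), seq(1L, W, 2L), , drop = FALSE] +
   x[seq(1L, H, 2L), seq(2L, W, 2L), , drop = FALSE] +
   x[seq(2L, H, 2L), seq(2L, W, 2L), , drop = FALSE]) / 4
}

#' Compact convolutional backbone
#'
#' Three convolution blocks (3x3 kernels, ReLU, 2x2 average pooling) with
#' fixed He-initialised random filters drawn from `seed`. The feature vector
#' concatenates the global average and the global maximum of each final
#' feature map: the average captures frame-wide attributes while the maximum
#' preserves small localised cues, which matter for fine-grained categories
#' that differ only in a small marking. Because the filters are fixed, the
#' backbone is a deterministic feature extractor and training reduces to
#' fitting the softmax heads — the transfer-learning regime in which a
#' pretrained convolutional trunk is frozen and only the replaced top layers
#' are learned.
#'
#' @param resolution square input size in pixels.
#' @param featureDim feature length (must be even; the last block has
#'   `featureDim / 2` channels, pooled twice).
#' @param channels channel widths of the three blocks; the last entry is
#'   overridden by `featureDim / 2`.
#' @param seed filter-initialisation seed.
#' @return a [Backbone-class].
#' @export
tinyBackbone <- function(resolution = 32L, featureDim = 64L,
                         channels = c(16L, 32L, 32L), seed = 1L) {
  if (featureDim %% 2L != 0L) stopf("featureDim must be even")
  channels[length(channels)] <- featureDim %/% 2L
  cin <- c(3L, channels[-length(channels)])
  filters <- withSeed(deriveSeed(seed, 97L), lapply(seq_along(channels), function(i) {
    fanIn <- 9L * cin[i]
    list(W = array(stats::rnorm(9L * cin[i] * channels[i], sd = sqrt(2 / fanIn)),
                   c(3L, 3L, cin[i], channels[i])),
         b = numeric(channels[i]))
  }))
  fwd <- function(images) {
    feats <- vapply(images, function(img) {
      x <- img
      for (f in filters) {
        x <- conv2dSame(x, f$W, f$b)
        x[x < 0] <- 0
        x <- avgPool2(x)
      }
      c(apply(x, 3L, mean), apply(x, 3L, max))
    }, numeric(featureDim))
    t(matrix(feats, nrow = featureDim))
  }
  new("Backbone", name = "tinycnn", inputResolution = as.numeric(resolution),
      featureDim = as.numeric(featureDim), forward = fwd)
}

#' Identity backbone over flattened pixels
#'
#' Returns the raw flattened pixel values as features; useful for analytic
#' tests where the feature map must be transparent.
#'
#' @param resolution square input size in pixels.
#' @return a [Backbone-class] with `featureDim = resolution^2 * 3`.
#' @export
pixelBackbone <- function(resolution = 16L) {
  fd <- as.numeric(resolution)^2 * 3
  new("Backbone", name = "pixels", inputResolution = as.numeric(resolution),
      featureDim = fd,
      forward = function(images) t(vapply(images, as.numeric, numeric(fd))))
}

#' Extract backbone features for a set of records
#'
#' Loads (and, for augmented records, replays) every image and pushes it
#' through the backbone.
#'
#' @param backbone a [Backbone-class].
#' @param recs data.frame of records.
#' @param imageRoot image directory.
#' @param policy augmentation policy used to replay augmented records.
#' @return n x featureDim matrix.
#' @export
backboneFeatures <- function(backbone, recs, imageRoot = ".", policy = NULL) {
  imgs <- lapply(seq_len(nrow(recs)), function(i)
    loadImage(recs[i, , drop = FALSE], backbone@inputResolution, imageRoot, policy))
  backbone@forward(imgs)
}
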