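#' Numerically stable softmax
#'
#' `softmax(z)_i = exp(z_i) / sum_j exp(z_j)`, computed with max subtraction.
#' For a matrix, the softmax is taken along each row.
#'
#' @param z finite numeric vector of logits, or a matrix of row logits.
#' @return probability vector (or matrix of row-probability vectors) summing
#'   to 1.
#' @examples
#' softmax(c(0, log(2)))  # 1/3, 2/3
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    if (ncol(z) == 0L) stopf("softmax of an empty vector")
    z <- z - apply(z, 1L, max)
    e <- exp(z)
    return(e / rowSums(e))
  }
  if (length(z) == 0L) stopf("softmax of an empty vector")
  e <- exp(z - max(z))
  e / sum(e)
}

#' Head layout constructors
#'
#' `headLayout()` builds a layout from explicit widths; `layoutFromTree()`
#' derives it from a taxonomy: a multilevel layout has one head per rank with
#' the rank's category count as width, a flat layout has a single head over
#' the finest rank.
#'
#' @param kind "flat" or "multilevel".
#' @param sizes head widths (flat: a single width).
#' @param names head names.
#' @return a [HeadLayout-class].
#' @export
headLayout <- function(kind, sizes, names = paste0("level", seq_along(sizes) - 1L)) {
  new("HeadLayout", kind = kind, levelSizes = as.numeric(sizes),
      levelNames = as.character(names))
}

#' @rdname headLayout
#' @param tree a [TaxonomyTree-class].
#' @export
layoutFromTree <- function(tree, kind = c("multilevel", "flat")) {
  kind <- match.arg(kind)
  s <- levelSizes(tree)
  if (kind == "flat")
    headLayout("flat", s[length(s)], levelNames(tree)[length(s)])
  else
    headLayout("multilevel", s, levelNames(tree))
}

#' Build a flat or multilevel classifier
#'
#' Attaches the requested head layout to a shared backbone: each head is a
#' fully connected layer with softmax over one rank's categories, and all
#' heads consume the same backbone feature vector. Heads are initialised with
#' small seeded Gaussian weights.
#'
#' @param backbone a [Backbone-class].
#' @param layout a [HeadLayout-class].
#' @param tree optional [TaxonomyTree-class]; when given, the layout widths
#'   are checked against the taxonomy and a mismatch is a configuration error.
#' @param seed head-initialisation seed.
#' @return an untrained [MultilevelModel-class].
#' @export
buildClassifier <- function(backbone, layout, tree = NULL, seed = 1L) {
  if (!is.null(tree)) {
    s <- levelSizes(tree)
    want <- if (layout@kind == "flat") s[length(s)] else s
    if (!identical(as.numeric(want), as.numeric(layout@levelSizes)))
      stopf("head layout (%s) does not match taxonomy level sizes (%s)",
            paste(layout@levelSizes, collapse = "/"), paste(s, collapse = "/"))
  }
  d <- backbone@featureDim
  heads <- withSeed(deriveSeed(seed, 11L), lapply(layout@levelSizes, function(K) {
    list(W = matrix(stats::rnorm(d * K, sd = 0.01), d, K), b = numeric(K))
  }))
  new("MultilevelModel", backbone = backbone, layout = layout, heads = heads,
      featCenter = numeric(d), featScale = rep(1, d), trained = FALSE)
}

standardizeFeatures <- function(X, center, scale) {
  sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
}

headProbs <- function(model, X) {
  Xs <- standardizeFeatures(X, model@featCenter, model@featScale)
  lapply(model@heads, function(h) {
    p <- softmax(Xs %*% h$W + matrix(h$b, nrow(Xs), length(h$b), byrow = TRUE))
    dimnames(p) <- NULL
    p
  })
}

#' Predict per-rank probabilities for a batch of images
#'
#' @param model a [MultilevelModel-class].
#' @param images list of H x W x 3 arrays, or a precomputed n x featureDim
#'   feature matrix.
#' @return a [PredictionSet-class].
#' @export
predictImages <- function(model, images) {
  X <- if (is.matrix(images)) images else model@backbone@forward(images)
  new("PredictionSet", probs = headProbs(model, X),
      levelNames = model@layout@levelNames)
}

#' @describeIn predictImages `predict` method.
#' @param object a [MultilevelModel-class].
#' @param newdata list of images or a feature matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "MultilevelModel",
          function(object, newdata, ...) predictImages(object, newdata))

#' Multilevel categorical cross-entropy
#'
#' The per-sample loss is the unweighted sum over levels of
#' `-log p_level[truth_level]`; a batch returns the mean of per-sample
#' losses. The loss is zero iff every head puts probability 1 on the true
#' category, and is invariant to permuting the levels.
#'
#' @param pred a [PredictionSet-class].
#' @param truth integer matrix (samples x levels) of 0-based true ids, or a
#'   vector for a single sample.
#' @param levelWeights optional per-level weights (default: all 1).
#' @return mean loss (non-negative scalar).
#' @export
multilevelLoss <- function(pred, truth, levelWeights = NULL) {
  if (!is.matrix(truth)) truth <- matrix(truth, nrow = 1L)
  L <- nLevels(pred)
  if (ncol(truth) != L) stopf("truth has %d levels, prediction has %d", ncol(truth), L)
  if (is.null(levelWeights)) levelWeights <- rep(1, L)
  n <- nrow(truth)
  tot <- numeric(n)
  for (i in seq_len(L)) {
    p <- pred@probs[[i]]
    if (any(truth[, i] < 0L) || any(truth[, i] >= ncol(p)))
      stopf("truth id out of range at level %d", i)
    tot <- tot - levelWeights[i] * log(pmax(p[cbind(seq_len(n), truth[, i] + 1L)], 1e-12))
  }
  mean(tot)
}

#' Early-stopping scan of an accuracy trace
#'
#' Halts once `patience` consecutive evaluations fail to exceed the best
#' value seen so far by more than `minDelta`, and reports the index of the
#' best checkpoint.
#'
#' @param trace numeric vector of test-set accuracies, one per evaluation.
#' @param patience number of consecutive non-improving evaluations tolerated.
#' @param minDelta improvement below or equal to this margin counts as "no
#'   significant improvement" (default 0).
#' @return list with `halted` (logical), `haltIndex` (evaluation at which
#'   training stops, NA if never), and `bestIndex`.
#' @export
earlyStopper <- function(trace, patience = 10L, minDelta = 0) {
  if (length(trace) == 0L) return(list(halted = FALSE, haltIndex = NA_integer_,
                                       bestIndex = NA_integer_))
  best <- trace[1L]; bestIdx <- 1L; bad <- 0L
  if (patience == 0L)
    return(list(halted = TRUE, haltIndex = 1L, bestIndex = 1L))
  for (i in seq_along(trace)[-1L]) {
    if (trace[i] > best + minDelta) {
      best <- trace[i]; bestIdx <- i; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience)
        return(list(halted = TRUE, haltIndex = i, bestIndex = bestIdx))
    }
  }
  list(halted = FALSE, haltIndex = NA_integer_, bestIndex = bestIdx)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4,
#' categorical cross-entropy, an evaluation on the test split every 10
#' epochs, and early stopping after 10 consecutive evaluations with no
#' significant improvement (`minDelta = 0`; "significant" is deliberately a
#' knob). `maxEpochs` bounds the nominally endless loop. Note that
#' evaluating on the test split during training mirrors the reference
#' protocol, which uses no validation split; pass `monitorSplit = "train"`
#' or carve out a validation split upstream for a leakage-free setup.
#'
#' @param learningRate Adam step size.
#' @param batchSize minibatch size.
#' @param testIntervalEpochs epochs between evaluations.
#' @param patienceTests early-stopping patience, in evaluations.
#' @param minDelta significant-improvement margin.
#' @param maxEpochs hard cap on epochs.
#' @param seed seed for shuffling and head initialisation.
#' @param amsgrad use the AMSGrad variant of Adam.
#' @param levelWeights optional per-level loss weights.
#' @param monitorSplit split used for the early-stopping metric.
#' @return a list with class `"TrainConfig"`.
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 32L,
                        testIntervalEpochs = 10L, patienceTests = 10L,
                        minDelta = 0, maxEpochs = 1000L, seed = 1L,
                        amsgrad = FALSE, levelWeights = NULL,
                        monitorSplit = "test") {
  stopifnot(learningRate > 0, testIntervalEpochs >= 1, batchSize >= 1)
  structure(list(learningRate = learningRate, batchSize = as.integer(batchSize),
                 testIntervalEpochs = as.integer(testIntervalEpochs),
                 patienceTests = as.integer(patienceTests), minDelta = minDelta,
                 maxEpochs = as.integer(maxEpochs), seed = as.integer(seed),
                 amsgrad = amsgrad, levelWeights = levelWeights,
                 monitorSplit = monitorSplit),
            class = "TrainConfig")
}

adamInit <- function(heads) lapply(heads, function(h)
  list(mW = h$W * 0, vW = h$W * 0, vhatW = h$W * 0,
       mb = h$b * 0, vb = h$b * 0, vhatb = h$b * 0))

adamStep <- function(h, st, gW, gb, lr, t, amsgrad,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  st$mW <- beta1 * st$mW + (1 - beta1) * gW
  st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
  st$mb <- beta1 * st$mb + (1 - beta1) * gb
  st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  if (amsgrad) {
    st$vhatW <- pmax(st$vhatW, st$vW); st$vhatb <- pmax(st$vhatb, st$vb)
    vW <- st$vhatW; vb <- st$vhatb
  } else {
    vW <- st$vW; vb <- st$vb
  }
  h$W <- h$W - lr * (st$mW / c1) / (sqrt(vW / c2) + eps)
  h$b <- h$b - lr * (st$mb / c1) / (sqrt(vb / c2) + eps)
  list(h = h, st = st)
}

# Core head trainer: fits the per-level softmax heads on a fixed feature
# matrix with Adam, epoch shuffling, periodic evaluation and early stopping.
# Used both for classifier training (X = backbone features) and for the
# stacking meta-layer (X = member log-probabilities).
trainHeads <- function(heads, X, Y, Xmon, Ymon, config, levelWeights = NULL) {
  L <- length(heads)
  n <- nrow(X)
  if (is.null(levelWeights)) levelWeights <- rep(1, L)
  st <- adamInit(heads)
  trace <- numeric(0)
  best <- list(heads = heads, index = 0L)
  logRows <- list()
  t <- 0L
  halted <- FALSE
  withSeed(deriveSeed(config$seed, 23L), {
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batchSize)
      for (s in starts) {
        idx <- ord[s:min(s + config$batchSize - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        t <- t + 1L
        for (l in seq_len(L)) {
          logits <- Xb %*% heads[[l]]$W +
            matrix(heads[[l]]$b, length(idx), length(heads[[l]]$b), byrow = TRUE)
          P <- softmax(logits)
          P[cbind(seq_along(idx), Y[[l]][idx] + 1L)] <-
            P[cbind(seq_along(idx), Y[[l]][idx] + 1L)] - 1
          G <- P * (levelWeights[l] / length(idx))
          up <- adamStep(heads[[l]], st[[l]], crossprod(Xb, G), colSums(G),
                         config$learningRate, t, config$amsgrad)
          heads[[l]] <- up$h; st[[l]] <- up$st
        }
      }
      if (epoch %% config$testIntervalEpochs == 0L) {
        ev <- evalHeads(heads, Xmon, Ymon, levelWeights)
        trace <- c(trace, ev$monitor)
        ti <- length(trace)
        for (l in seq_len(L))
          logRows[[length(logRows) + 1L]] <- data.frame(
            test_index = ti, epoch = epoch, level = l,
            top1 = ev$top1[l], top5 = ev$top5[l], loss = ev$loss)
        es <- earlyStopper(trace, config$patienceTests, config$minDelta)
        if (!is.na(es$bestIndex) && es$bestIndex == ti)
          best <- list(heads = heads, index = ti)
        if (es$halted) { halted <- TRUE; break }
      }
    }
  })
  if (best$index == 0L) best <- list(heads = heads, index = length(trace))
  log <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame(test_index = integer(0), epoch = integer(0), level = integer(0),
               top1 = numeric(0), top5 = numeric(0), loss = numeric(0))
  list(heads = best$heads, lastHeads = heads, trace = trace, log = log,
       halted = halted, bestIndex = best$index)
}

evalHeads <- function(heads, X, Y, levelWeights) {
  L <- length(heads)
  n <- nrow(X)
  top1 <- top5 <- numeric(L)
  loss <- 0
  for (l in seq_len(L)) {
    P <- softmax(X %*% heads[[l]]$W +
                 matrix(heads[[l]]$b, n, length(heads[[l]]$b), byrow = TRUE))
    top1[l] <- topkFromProbs(P, Y[[l]], 1L)
    top5[l] <- topkFromProbs(P, Y[[l]], min(5L, ncol(P)))
    loss <- loss + levelWeights[l] *
      mean(-log(pmax(P[cbind(seq_len(n), Y[[l]] + 1L)], 1e-12)))
  }
  list(top1 = top1, top5 = top5, loss = loss, monitor = top1[L])
}

topkFromProbs <- function(P, y, k) {
  n <- nrow(P)
  hits <- vapply(seq_len(n), function(i) {
    topk <- order(-P[i, ], seq_len(ncol(P)))[seq_len(k)]
    (y[i] + 1L) %in% topk
  }, TRUE)
  mean(hits)
}

#' Train a multilevel (or flat) classifier
#'
#' Extracts backbone features for the train and monitor splits (replaying any
#' augmented records lazily), standardises them with the training-split mean
#' and standard deviation, and fits the softmax heads with Adam under
#' categorical cross-entropy. The monitor split is evaluated every
#' `testIntervalEpochs` epochs; training halts via [earlyStopper()] and the
#' best checkpoint (finest-level top-1 on the monitor split) is returned.
#'
#' @param model an untrained [MultilevelModel-class] from [buildClassifier()].
#' @param manifest a [DatasetManifest-class] with train and test records.
#' @param config a [trainConfig()].
#' @param policy augmentation policy used to replay augmented records.
#' @param trainRecords optional replacement train record table (used by the
#'   cascade to train specialists on relabelled subsets).
#' @param monitorRecords optional replacement monitor record table.
#' @param trainLabels,monitorLabels optional 0-based label matrices matching
#'   the layout (needed whenever the layout's label spaces differ from the
#'   manifest taxonomy, e.g. cascade specialists).
#' @return list with `model` (best checkpoint), `log` (data.frame with one
#'   row per level per evaluation), `trace` (monitor values) and `halted`.
#' @export
trainModel <- function(model, manifest, config = trainConfig(), policy = NULL,
                       trainRecords = NULL, trainLabels = NULL,
                       monitorRecords = NULL, monitorLabels = NULL) {
  df <- records(manifest)
  trainDf <- if (is.null(trainRecords)) df[df$split == "train", , drop = FALSE]
             else trainRecords
  monDf <- if (is.null(monitorRecords))
    df[df$split == config$monitorSplit, , drop = FALSE] else monitorRecords
  if (nrow(trainDf) == 0L) stopf("trainModel: empty train split")
  if (nrow(monDf) == 0L) stopf("trainModel: empty %s split", config$monitorSplit)
  X <- backboneFeatures(model@backbone, trainDf, manifest@imageRoot, policy)
  Xm <- backboneFeatures(model@backbone, monDf, manifest@imageRoot, policy)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-8] <- 1
  model@featCenter <- ctr
  model@featScale <- scl
  Xs <- standardizeFeatures(X, ctr, scl)
  Xms <- standardizeFeatures(Xm, ctr, scl)
  Ytr <- labelsForLayout(model@layout, trainDf, trainLabels, nLevels(manifest))
  Ymn <- labelsForLayout(model@layout, monDf, monitorLabels, nLevels(manifest))
  heads <- withSeed(deriveSeed(config$seed, 11L), lapply(model@layout@levelSizes,
    function(K) list(W = matrix(stats::rnorm(model@backbone@featureDim * K, sd = 0.01),
                                model@backbone@featureDim, K),
                     b = numeric(K))))
  fit <- trainHeads(heads, Xs, Ytr, Xms, Ymn, config, config$levelWeights)
  model@heads <- fit$heads
  model@trained <- TRUE
  lev <- model@layout@levelNames
  if (nrow(fit$log)) fit$log$level <- lev[fit$log$level]
  list(model = model, log = fit$log, trace = fit$trace, halted = fit$halted,
       bestIndex = fit$bestIndex)
}

labelsForLayout <- function(layout, df, override, Ltree) {
  L <- length(layout@levelSizes)
  if (!is.null(override)) {
    if (!is.matrix(override)) override <- matrix(override, ncol = L)
    return(lapply(seq_len(L), function(i) as.integer(override[, i])))
  }
  if (layout@kind == "flat")
    return(list(as.integer(df[[paste0("label_level", Ltree - 1L)]])))
  lapply(seq_len(L), function(i) as.integer(df[[paste0("label_level", i - 1L)]]))
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint is a single RDS archive holding the model (weights, head
#' layout, backbone spec), the taxonomy, and the training configuration.
#'
#' @param model a [MultilevelModel-class].
#' @param tree the [TaxonomyTree-class] trained against.
#' @param config the [trainConfig()] used.
#' @param path file path.
#' @return `path` invisibly (`saveCheckpoint`); a list with `model`, `tree`,
#'   `config` (`loadCheckpoint`).
#' @export
saveCheckpoint <- function(model, tree, config, path) {
  saveRDS(list(model = model, tree = tree, config = config), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)
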