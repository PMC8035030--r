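# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately written with plain loops, separate from the package's
# vectorised implementations.

oracle_topk <- function(P, y, k) {
  hits <- 0L
  for (i in seq_len(nrow(P))) {
    ord <- order(-P[i, ], seq_len(ncol(P)))
    if ((y[i] + 1L) %in% ord[seq_len(k)]) hits <- hits + 1L
  }
  hits / nrow(P)
}

oracle_f1 <- function(P, y) {
  K <- ncol(P)
  yhat <- integer(nrow(P))
  for (i in seq_len(nrow(P))) yhat[i] <- which.max(P[i, ]) - 1L
  f1 <- prec <- rec <- numeric(K)
  support <- numeric(K)
  for (c in seq_len(K) - 1L) {
    tp <- sum(y == c & yhat == c); fp <- sum(y != c & yhat == c)
    fn <- sum(y == c & yhat != c)
    prec[c + 1L] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c + 1L] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c + 1L] <- if (prec[c + 1L] + rec[c + 1L] > 0)
      2 * prec[c + 1L] * rec[c + 1L] / (prec[c + 1L] + rec[c + 1L]) else 0
    support[c + 1L] <- sum(y == c)
  }
  keep <- support > 0
  list(f1 = f1, weighted = sum(f1[keep] * support[keep]) / sum(support[keep]))
}

# pairwise concordance AUC: ties count 1/2
oracle_auc_binary <- function(score, pos) {
  ps <- score[pos]; ns <- score[!pos]
  if (!length(ps) || !length(ns)) return(NA_real_)
  tot <- 0
  for (a in ps) for (b in ns)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

oracle_macro_auc <- function(P, y) {
  aucs <- c()
  for (c in seq_len(ncol(P)) - 1L) {
    a <- oracle_auc_binary(P[, c + 1L], y == c)
    if (!is.na(a)) aucs <- c(aucs, a)
  }
  mean(aucs)
}

oracle_boost <- function(members, weights) {
  L <- length(members[[1]]@probs)
  lapply(seq_len(L), function(l) {
    s <- 0
    for (m in seq_along(members)) s <- s + weights[m, l] * members[[m]]@probs[[l]]
    s / rowSums(s)
  })
}

oracle_nearest_centroid <- function(Xtrain, ytrain, Xtest) {
  cls <- sort(unique(ytrain))
  cent <- t(vapply(cls, function(c) colMeans(Xtrain[ytrain == c, , drop = FALSE]),
                   numeric(ncol(Xtrain))))
  apply(Xtest, 1L, function(x) cls[which.min(colSums((t(cent) - x)^2))])
}

# random valid PredictionSet over given level sizes
random_predset <- function(n, sizes, seed = 1) {
  withr::with_seed(seed, {
    probs <- lapply(sizes, function(K) {
      m <- matrix(stats::rexp(n * K), n, K)
      m / rowSums(m)
    })
    new("PredictionSet", probs = probs,
        levelNames = paste0("level", seq_along(sizes) - 1L))
  })
}

# flatten images of a manifest split to a pixel matrix
pixel_matrix <- function(manifest, split, resolution) {
  df <- records(manifest)
  df <- df[df$split == split, , drop = FALSE]
  t(vapply(seq_len(nrow(df)), function(i)
    as.numeric(loadImage(df[i, , drop = FALSE], resolution, manifest@imageRoot)),
    numeric(resolution^2 * 3)))
}

# small iNaturalist-dialect annotation fixture on disk; returns the json path
write_inat_fixture <- function(dir, break_category = FALSE, drop_rank = FALSE) {
  cats <- data.frame(
    id = c(11L, 22L),
    kingdom = c("Animalia", "Plantae"),
    phylum = c("Chordata", "Tracheophyta"),
    class = c("Aves", "Liliopsida"),
    order = c("Passeriformes", "Asparagales"),
    family = c("Turdidae", "Orchidaceae"),
    genus = c("Turdus", "Orchis"),
    name = c("Turdus merula", "Orchis mascula"),
    stringsAsFactors = FALSE)
  if (drop_rank) cats$family <- NULL
  ann <- data.frame(id = 1:2, image_id = c(100L, 200L),
                    category_id = c(11L, if (break_category) 99L else 22L))
  doc <- list(
    images = data.frame(id = c(100L, 200L),
                        file_name = c("a.png", "b.png"),
                        stringsAsFactors = FALSE),
    annotations = ann,
    categories = cats)
  p <- file.path(dir, "annotations.json")
  jsonlite::write_json(doc, p, dataframe = "rows", auto_unbox = TRUE)
  p
}

# session-cached tiny noiseless dataset (branching 2x2, 40 images). The
# subject fills the frame so the class-coding pixels are aligned and a
# raw-pixel nearest-centroid classifier attains 1.0 leaf accuracy — the
# separability precondition the trainability checks build on.
.fixture_env <- new.env(parent = emptyenv())
clean_dataset <- function() {
  if (is.null(.fixture_env$clean)) {
    d <- file.path(tempdir(), "rv_clean_ds")
    spec <- syntheticSpec(c(2L, 2L), samplesPerLeaf = 10L, imageSize = 32L,
                          noiseSigma = 0, blurProb = 0,
                          subjectScaleRange = c(1, 1), seed = 11L)
    .fixture_env$clean <- generateDataset(spec, 0.8, d)
  }
  .fixture_env$clean
}

train_quick <- function(manifest, kind = "multilevel", seed = 1L,
                        lr = 0.05, maxEpochs = 300L, backbone = NULL) {
  if (is.null(backbone)) backbone <- tinyBackbone(32L, 64L, seed = seed)
  model <- buildClassifier(backbone, layoutFromTree(taxonomy(manifest), kind),
                           taxonomy(manifest), seed = seed)
  tc <- trainConfig(learningRate = lr, batchSize = 16L, testIntervalEpochs = 10L,
                    patienceTests = 10L, maxEpochs = maxEpochs, seed = seed)
  fit <- trainModel(model, manifest, tc)
  fit$backbone <- backbone
  fit
}
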