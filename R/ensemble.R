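# Ensemble schemes over fitted multilevel classifiers: accuracy-weighted
# boosting, a stacked fully connected meta-classifier, and a cascade that
# routes each sample through a coarse-rank classifier to a per-category
# specialist.

#' Measure per-member, per-level accuracy weights
#'
#' The boosting weight of a member at a level is its measured top-1 accuracy
#' at that level on an evaluation split.
#'
#' @param members list of [PredictionSet-class], one per member, on the same
#'   samples.
#' @param truth integer matrix (samples x levels) of 0-based true ids.
#' @return members x levels matrix of accuracies.
#' @export
measureWeights <- function(members, truth) {
  L <- nLevels(members[[1L]])
  w <- matrix(0, length(members), L)
  for (m in seq_along(members))
    for (l in seq_len(L))
      w[m, l] <- topkFromProbs(members[[m]]@probs[[l]], truth[, l], 1L)
  w
}

#' Combine member predictions by accuracy-weighted voting (boosting)
#'
#' Per level, each member's probability vector is multiplied by its weight,
#' the weighted vectors are summed across members, and the sum is
#' renormalised; the argmax of the combined score (ties broken towards the
#' lowest category id) is the ensemble decision.
#'
#' @param members list of [PredictionSet-class] sharing level sizes.
#' @param weights numeric vector with one weight per member (applied to every
#'   level), or a members x levels matrix for per-level weighting.
#' @return the combined [PredictionSet-class].
#' @export
boostCombine <- function(members, weights) {
  if (length(members) < 1L) stopf("boostCombine needs at least one member")
  L <- nLevels(members[[1L]])
  sizes <- levelSizes(members[[1L]])
  for (m in members[-1L])
    if (!identical(levelSizes(m), sizes))
      stopf("members disagree on level sizes")
  if (!is.matrix(weights)) weights <- matrix(weights, length(members), L)
  if (any(weights < 0)) stopf("weights must be nonnegative")
  if (any(colSums(weights) <= 0))
    stopf("every level needs at least one member with positive weight")
  probs <- lapply(seq_len(L), function(l) {
    acc <- 0
    for (m in seq_along(members)) acc <- acc + weights[m, l] * members[[m]]@probs[[l]]
    acc / rowSums(acc)
  })
  new("PredictionSet", probs = probs, levelNames = members[[1L]]@levelNames)
}

stackInput <- function(members) {
  do.call(cbind, lapply(members, function(m)
    do.call(cbind, lapply(m@probs, function(p) log(pmax(p, 1e-12))))))
}

#' Fit a stacking meta-classifier on frozen member outputs
#'
#' The meta-model is a single fully connected layer with one softmax group
#' per level. Its input is the concatenation of every member's per-level
#' log-probabilities (width `sum(members) * sum(levelSizes)`), so with
#' `identityInit = TRUE` and a single member the untrained stack reproduces
#' that member exactly. Training uses the same Adam machinery as the
#' classifier heads.
#'
#' @param members list of [PredictionSet-class] on the fitting split.
#' @param truth integer matrix (samples x levels) of 0-based true ids.
#' @param config a [trainConfig()]; `maxEpochs = 0` skips fitting.
#' @param identityInit initialise head `l` as the identity over member 1's
#'   level-`l` block instead of small random weights.
#' @return a [StackModel-class].
#' @export
fitStacking <- function(members, truth, config = trainConfig(learningRate = 0.05),
                        identityInit = FALSE) {
  if (length(members) < 1L) stopf("stacking needs at least one member")
  sizes <- levelSizes(members[[1L]])
  for (m in members[-1L])
    if (!identical(levelSizes(m), sizes)) stopf("members disagree on level sizes")
  L <- length(sizes)
  X <- stackInput(members)
  d <- ncol(X)
  offs <- cumsum(c(0L, sizes))
  heads <- withSeed(deriveSeed(config$seed, 31L), lapply(seq_len(L), function(l) {
    W <- matrix(stats::rnorm(d * sizes[l], sd = 0.01), d, sizes[l])
    if (identityInit) {
      W[] <- 0
      for (j in seq_len(sizes[l])) W[offs[l] + j, j] <- 1
    }
    list(W = W, b = numeric(sizes[l]))
  }))
  Y <- lapply(seq_len(L), function(l) as.integer(truth[, l]))
  if (config$maxEpochs > 0L) {
    fit <- trainHeads(heads, X, Y, X, Y, config, config$levelWeights)
    heads <- fit$heads
  }
  new("StackModel", heads = heads, levelSizes = as.numeric(sizes),
      levelNames = members[[1L]]@levelNames, nMembers = length(members))
}

#' Apply a stacking meta-classifier
#'
#' @param stack a [StackModel-class] from [fitStacking()].
#' @param members list of [PredictionSet-class] for the samples to combine.
#' @return the stacked [PredictionSet-class].
#' @export
stackCombine <- function(stack, members) {
  if (length(members) != stack@nMembers)
    stopf("stack was fitted on %d members, got %d", stack@nMembers, length(members))
  X <- stackInput(members)
  probs <- lapply(stack@heads, function(h)
    softmax(X %*% h$W + matrix(h$b, nrow(X), length(h$b), byrow = TRUE)))
  probs <- lapply(probs, function(p) { dimnames(p) <- NULL; p })
  new("PredictionSet", probs = probs, levelNames = stack@levelNames)
}

ancestorAtLevel <- function(tree, level, fromLevel) {
  # ancestor id at `level` for every node of `fromLevel`
  ids <- seq_len(levelSizes(tree)[fromLevel]) - 1L
  while (fromLevel > level) {
    ids <- tree@parent[[fromLevel]][ids + 1L]
    fromLevel <- fromLevel - 1L
  }
  ids
}

#' Label-space layout of a routed cascade
#'
#' For each category of the routing level, lists the global ids of its
#' descendants at every finer level; these define the subtree-local label
#' spaces of the specialists.
#'
#' @param tree a [TaxonomyTree-class].
#' @param routingLevel 1-based routing level index (e.g. 2 for Phylum in a
#'   Kingdom..Species taxonomy).
#' @return list with `routingLevel`, `nSpecialists`, and `localToGlobal` —
#'   one list per routing category of per-finer-level global id vectors.
#' @export
cascadeLayout <- function(tree, routingLevel) {
  L <- nLevels(tree)
  if (routingLevel < 1L || routingLevel > L) stopf("invalid routing level")
  R <- levelSizes(tree)[routingLevel]
  finer <- seq_len(L)[seq_len(L) > routingLevel]
  localToGlobal <- lapply(seq_len(R) - 1L, function(r) {
    lapply(finer, function(l) {
      anc <- ancestorAtLevel(tree, routingLevel, l)
      which(anc == r) - 1L
    })
  })
  list(routingLevel = routingLevel, nSpecialists = R,
       finerLevels = finer, localToGlobal = localToGlobal)
}

#' Train a routed cascade of classifiers
#'
#' Trains a router on the routing-level labels of the full training split,
#' and one specialist per routing category on only the records whose true
#' routing-level label matches, with label spaces reindexed to the subtree.
#'
#' @param manifest a [DatasetManifest-class].
#' @param routingLevel 1-based routing level index.
#' @param backbone shared [Backbone-class] for router and specialists.
#' @param config a [trainConfig()].
#' @param policy augmentation policy for replaying augmented records.
#' @return a [CascadeModel-class].
#' @export
buildCascade <- function(manifest, routingLevel, backbone,
                         config = trainConfig(), policy = NULL) {
  tree <- taxonomy(manifest)
  L <- nLevels(tree)
  lay <- cascadeLayout(tree, routingLevel)
  df <- records(manifest)
  rCol <- paste0("label_level", routingLevel - 1L)
  routerLayout <- headLayout("multilevel", levelSizes(tree)[routingLevel],
                             levelNames(tree)[routingLevel])
  router <- buildClassifier(backbone, routerLayout, seed = config$seed)
  routerFit <- trainModel(router, manifest, config, policy,
                          trainLabels = matrix(df[df$split == "train", rCol], ncol = 1L),
                          monitorLabels = matrix(df[df$split == config$monitorSplit, rCol],
                                                 ncol = 1L))
  specialists <- vector("list", lay$nSpecialists)
  for (r in seq_len(lay$nSpecialists) - 1L) {
    sub <- df[df$split == "train" & df[[rCol]] == r, , drop = FALSE]
    if (nrow(sub) == 0L)
      stopf("routing category '%s' has no training records",
            tree@names[[routingLevel]][r + 1L])
    mon <- df[df$split == config$monitorSplit & df[[rCol]] == r, , drop = FALSE]
    if (nrow(mon) == 0L) mon <- sub
    l2g <- lay$localToGlobal[[r + 1L]]
    sizes <- vapply(l2g, length, 1L)
    specLayout <- headLayout("multilevel", sizes, levelNames(tree)[lay$finerLevels])
    toLocal <- function(d) {
      m <- matrix(0L, nrow(d), length(lay$finerLevels))
      for (j in seq_along(lay$finerLevels)) {
        gl <- d[[paste0("label_level", lay$finerLevels[j] - 1L)]]
        m[, j] <- match(gl, l2g[[j]]) - 1L
      }
      m
    }
    spec <- buildClassifier(backbone, specLayout, seed = deriveSeed(config$seed, r))
    specFit <- trainModel(spec, manifest, config, policy,
                          trainRecords = sub, trainLabels = toLocal(sub),
                          monitorRecords = mon, monitorLabels = toLocal(mon))
    specialists[[r + 1L]] <- specFit$model
  }
  new("CascadeModel", tree = tree, routingLevel = as.numeric(routingLevel),
      router = routerFit$model, specialists = specialists,
      localToGlobal = lapply(lay$localToGlobal, identity))
}

#' Predict with a routed cascade
#'
#' The router's argmax (ties to the lowest id) selects a specialist; the
#' specialist's subtree-local probabilities are mapped back to global ids
#' with probability exactly 0 outside the routed subtree. Levels coarser
#' than the routing level are filled deterministically from the taxonomy
#' ancestor path of the routed category; the routing level carries the
#' router's probability vector.
#'
#' @param cascade a [CascadeModel-class].
#' @param images list of images or a feature matrix from the shared backbone.
#' @param routingProbs optional samples x routingCategories matrix overriding
#'   the router's output (e.g. cached or perturbed routing decisions).
#' @return a [PredictionSet-class] over all taxonomy levels.
#' @export
cascadePredict <- function(cascade, images, routingProbs = NULL) {
  tree <- cascade@tree
  L <- nLevels(tree)
  rl <- as.integer(cascade@routingLevel)
  sizes <- levelSizes(tree)
  X <- if (is.matrix(images)) images else cascade@router@backbone@forward(images)
  n <- nrow(X)
  if (is.null(routingProbs))
    routingProbs <- predictImages(cascade@router, X)@probs[[1L]]
  routed <- max.col(routingProbs, ties.method = "first") - 1L
  finer <- seq_len(L)[seq_len(L) > rl]
  probs <- vector("list", L)
  for (l in seq_len(L)) probs[[l]] <- matrix(0, n, sizes[l])
  probs[[rl]] <- routingProbs
  for (r in sort(unique(routed))) {
    idx <- which(routed == r)
    sp <- predictImages(cascade@specialists[[r + 1L]], X[idx, , drop = FALSE])
    l2g <- cascade@localToGlobal[[r + 1L]]
    for (j in seq_along(finer))
      probs[[finer[j]]][idx, l2g[[j]] + 1L] <- sp@probs[[j]]
    # coarser levels: deterministic from the routed category's ancestor path
    anc <- r
    for (l in rev(seq_len(rl - 1L))) {
      anc <- tree@parent[[l + 1L]][anc + 1L]
      probs[[l]][idx, anc + 1L] <- 1
    }
  }
  new("PredictionSet", probs = probs, levelNames = levelNames(tree))
}
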