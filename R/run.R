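# Configuration and end-to-end run plumbing. Every run resolves its
# configuration against the defaults, fans the global seed out into named
# sub-seeds (data / augment / model / shuffle), confines all outputs to its
# output directory, and writes the fully resolved configuration next to the
# outputs so the run is reproducible from that file alone.

#' Default run configuration
#'
#' @return named list of every configuration key with its default.
#' @export
runConfigDefaults <- function() {
  list(
    seed = 1L,
    outputDir = "rankvision_run",
    force = FALSE,
    # data
    dataset = NULL,            # directory containing manifest.csv (+ images)
    manifest = NULL,           # explicit manifest CSV path (overrides dataset)
    resolution = 32L,
    # synth
    branching = c(2L, 2L),
    samplesPerLeaf = 20L,
    imageSize = 32L,
    subjectScaleRange = c(0.3, 0.95),
    noiseSigma = 0.05,
    blurProb = 0.25,
    trainFraction = 0.8,
    # augment
    augmentation = "none",     # none | standard | central_crop | multiscale_crop
    # model
    backbone = "tinycnn",      # tinycnn | pixels
    featureDim = 64L,
    headKind = "multilevel",   # multilevel | flat
    learningRate = 1e-4,
    batchSize = 32L,
    testIntervalEpochs = 10L,
    patienceTests = 10L,
    minDelta = 0,
    maxEpochs = 300L,
    amsgrad = FALSE,
    # eval / ensemble
    split = "test",
    checkpoint = NULL,
    members = NULL,            # checkpoint paths for boosting/stacking
    ensembleMode = "boosting", # boosting | stacking | cascade
    weightSource = "carveout", # carveout | test
    carveFraction = 0.1,
    routingLevel = 2L,
    perLevelWeights = TRUE
  )
}

#' Resolve a run configuration
#'
#' Merges, in increasing precedence: the defaults, an optional YAML file, and
#' explicit overrides. Unknown keys are an error.
#'
#' @param file optional YAML configuration file.
#' @param ... overrides as named arguments.
#' @return resolved configuration list.
#' @export
resolveRunConfig <- function(file = NULL, ...) {
  cfg <- runConfigDefaults()
  apply1 <- function(cfg, vals, src) {
    bad <- setdiff(names(vals), names(cfg))
    if (length(bad)) stopf("unknown configuration key(s) in %s: %s", src,
                           paste(bad, collapse = ", "))
    utils::modifyList(cfg, vals)
  }
  if (!is.null(file)) cfg <- apply1(cfg, yaml::read_yaml(file), file)
  dots <- list(...)
  if (length(dots)) cfg <- apply1(cfg, dots, "overrides")
  if (!cfg$augmentation %in% c("none", "standard", "central_crop", "multiscale_crop"))
    stopf("invalid augmentation mode '%s'", cfg$augmentation)
  if (cfg$resolution < 1) stopf("resolution must be positive")
  cfg
}

writeResolvedConfig <- function(cfg, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg[order(names(cfg))], file.path(outputDir, "run_config.yaml"))
}

prepareOutputDir <- function(cfg) {
  od <- cfg$outputDir
  if (dir.exists(od) && length(list.files(od)) > 0L && !isTRUE(cfg$force))
    stopf("output directory '%s' is not empty (use force = TRUE)", od)
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  od
}

configBackbone <- function(cfg) {
  switch(cfg$backbone,
         tinycnn = tinyBackbone(cfg$resolution, cfg$featureDim,
                                seed = deriveSeed(cfg$seed, 3L)),
         pixels = pixelBackbone(cfg$resolution),
         stopf("unknown backbone '%s'", cfg$backbone))
}

configTrain <- function(cfg) {
  trainConfig(learningRate = cfg$learningRate, batchSize = cfg$batchSize,
              testIntervalEpochs = cfg$testIntervalEpochs,
              patienceTests = cfg$patienceTests, minDelta = cfg$minDelta,
              maxEpochs = cfg$maxEpochs, seed = deriveSeed(cfg$seed, 4L),
              amsgrad = cfg$amsgrad)
}

configPolicy <- function(cfg) {
  augmentPolicy(mode = cfg$augmentation, seed = deriveSeed(cfg$seed, 5L))
}

loadConfigManifest <- function(cfg) {
  if (!is.null(cfg$manifest))
    return(readManifestCSV(cfg$manifest))
  if (is.null(cfg$dataset)) stopf("no dataset or manifest configured")
  readManifestCSV(file.path(cfg$dataset, "manifest.csv"), imageRoot = cfg$dataset)
}

#' Generate a synthetic dataset from a run configuration
#'
#' @param cfg a configuration from [resolveRunConfig()].
#' @return the generated [DatasetManifest-class], invisibly.
#' @export
runSynth <- function(cfg) {
  od <- prepareOutputDir(cfg)
  spec <- syntheticSpec(branching = cfg$branching,
                        samplesPerLeaf = cfg$samplesPerLeaf,
                        imageSize = cfg$imageSize,
                        subjectScaleRange = cfg$subjectScaleRange,
                        noiseSigma = cfg$noiseSigma, blurProb = cfg$blurProb,
                        seed = deriveSeed(cfg$seed, 2L))
  manifest <- generateDataset(spec, cfg$trainFraction, od)
  writeResolvedConfig(cfg, od)
  df <- records(manifest)
  message(sprintf("synth: %s levels (%s), %d leaves, %d images (%d train / %d test) -> %s",
                  nLevels(manifest), paste(levelSizes(manifest), collapse = "/"),
                  levelSizes(manifest)[nLevels(manifest)], nrow(df),
                  sum(df$split == "train"), sum(df$split == "test"), od))
  invisible(manifest)
}

#' Train a classifier from a run configuration
#'
#' Runs the full pipeline: read manifest, apply the configured augmentation
#' and balancing regime, build the classifier, train it, and write the
#' checkpoint, the training log and the resolved configuration into the
#' output directory.
#'
#' @param cfg a configuration from [resolveRunConfig()].
#' @return list with `model`, `tree`, `log`, invisibly.
#' @export
runTrain <- function(cfg) {
  od <- prepareOutputDir(cfg)
  manifest <- loadConfigManifest(cfg)
  policy <- configPolicy(cfg)
  if (cfg$augmentation != "none") manifest <- balanceDataset(manifest, policy)
  tree <- taxonomy(manifest)
  backbone <- configBackbone(cfg)
  layout <- layoutFromTree(tree, cfg$headKind)
  model <- buildClassifier(backbone, layout, tree, seed = deriveSeed(cfg$seed, 6L))
  tc <- configTrain(cfg)
  fit <- trainModel(model, manifest, tc, policy)
  saveCheckpoint(fit$model, tree, tc, file.path(od, "checkpoint.rds"))
  utils::write.csv(fit$log, file.path(od, "training_log.csv"), row.names = FALSE)
  writeResolvedConfig(cfg, od)
  message(sprintf("train: %d head(s) (%s), %d evaluations, best test top-1 %.3f",
                  length(fit$model@heads),
                  paste(layout@levelSizes, collapse = "/"),
                  length(fit$trace), max(fit$trace)))
  invisible(list(model = fit$model, tree = tree, log = fit$log))
}

#' Evaluate a checkpoint from a run configuration
#'
#' @param cfg a configuration from [resolveRunConfig()]; needs `checkpoint`
#'   and `dataset`/`manifest`.
#' @return the [EvalReport-class], invisibly.
#' @export
runEval <- function(cfg) {
  od <- prepareOutputDir(cfg)
  ck <- loadCheckpoint(cfg$checkpoint)
  manifest <- loadConfigManifest(cfg)
  df <- records(manifest)
  sel <- df[df$split == cfg$split, , drop = FALSE]
  if (nrow(sel) == 0L) stopf("split '%s' is empty", cfg$split)
  X <- backboneFeatures(ck$model@backbone, sel, manifest@imageRoot)
  pred <- predictImages(ck$model, X)
  truth <- labelsMatrix(manifest, cfg$split)
  if (ck$model@layout@kind == "flat") truth <- truth[, nLevels(manifest), drop = FALSE]
  report <- evaluateModel(pred, truth)
  writeEvalReport(report, file.path(od, "eval"))
  writeResolvedConfig(cfg, od)
  message(sprintf("eval: %d samples, finest top-1 %.3f",
                  nrow(sel), report@perLevel$top1[nrow(report@perLevel)]))
  invisible(report)
}

carveOutSplit <- function(df, labCol, fraction, seed) {
  train <- which(df$split == "train")
  lab <- df[[labCol]][train]
  hold <- withSeed(seed, unlist(lapply(split(train, lab), function(idx) {
    n <- max(1L, round(length(idx) * fraction))
    idx[sample.int(length(idx), n)]
  })))
  list(hold = sort(hold), rest = setdiff(train, hold))
}

#' Build and evaluate an ensemble from a run configuration
#'
#' Boosting and stacking load at least two member checkpoints; their weights
#' (respectively the stack fit) are measured on a stratified carve-out of the
#' training split by default, or on the test split when
#' `weightSource = "test"`. Cascade mode trains a router and one specialist
#' per routing-level category. The combined predictions are evaluated on the
#' configured split and the report (including measured member weights for
#' boosting) is written to the output directory.
#'
#' @param cfg a configuration from [resolveRunConfig()].
#' @return list with `report` and mode-specific components, invisibly.
#' @export
runEnsemble <- function(cfg) {
  od <- prepareOutputDir(cfg)
  manifest <- loadConfigManifest(cfg)
  tree <- taxonomy(manifest)
  df <- records(manifest)
  truthEval <- labelsMatrix(manifest, cfg$split)
  evalRows <- df[df$split == cfg$split, , drop = FALSE]
  out <- list()
  if (cfg$ensembleMode %in% c("boosting", "stacking")) {
    if (is.null(cfg$members) || length(cfg$members) < 2L)
      stopf("%s needs at least 2 member checkpoints", cfg$ensembleMode)
    cks <- lapply(cfg$members, loadCheckpoint)
    labCol <- paste0("label_level", nLevels(manifest) - 1L)
    if (cfg$weightSource == "carveout") {
      cv <- carveOutSplit(df, labCol, cfg$carveFraction, deriveSeed(cfg$seed, 8L))
      fitRows <- df[cv$hold, , drop = FALSE]
    } else {
      fitRows <- evalRows
    }
    memberPreds <- function(rows) lapply(cks, function(ck) {
      X <- backboneFeatures(ck$model@backbone, rows, manifest@imageRoot)
      predictImages(ck$model, X)
    })
    fitTruth <- as.matrix(fitRows[, paste0("label_level",
                                           seq_len(nLevels(manifest)) - 1L)])
    onFit <- memberPreds(fitRows)
    onEval <- memberPreds(evalRows)
    if (cfg$ensembleMode == "boosting") {
      w <- measureWeights(onFit, fitTruth)
      if (!cfg$perLevelWeights) w <- matrix(rowMeans(w), nrow(w), ncol(w))
      combined <- boostCombine(onEval, w)
      out$weights <- w
      utils::write.csv(data.frame(member = rep(seq_along(cks), ncol(w)),
                                  level = rep(levelNames(tree), each = nrow(w)),
                                  weight = as.vector(w)),
                       file.path(od, "member_weights.csv"), row.names = FALSE)
    } else {
      stack <- fitStacking(onFit, fitTruth,
                           trainConfig(learningRate = 0.05, batchSize = 32L,
                                       testIntervalEpochs = 10L, patienceTests = 10L,
                                       maxEpochs = 200L,
                                       seed = deriveSeed(cfg$seed, 9L)))
      combined <- stackCombine(stack, onEval)
      out$stack <- stack
    }
  } else if (cfg$ensembleMode == "cascade") {
    backbone <- configBackbone(cfg)
    cascade <- buildCascade(manifest, cfg$routingLevel, backbone, configTrain(cfg),
                            configPolicy(cfg))
    saveRDS(cascade, file.path(od, "cascade.rds"))
    X <- backboneFeatures(backbone, evalRows, manifest@imageRoot)
    combined <- cascadePredict(cascade, X)
    out$cascade <- cascade
  } else {
    stopf("unknown ensemble mode '%s'", cfg$ensembleMode)
  }
  report <- evaluateModel(combined, truthEval)
  writeEvalReport(report, file.path(od, "ensemble_eval"))
  writeResolvedConfig(cfg, od)
  message(sprintf("ensemble (%s): finest top-1 %.3f", cfg$ensembleMode,
                  report@perLevel$top1[nrow(report@perLevel)]))
  out$report <- report
  invisible(out)
}
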