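test_that("softmax matches its closed form and invariances", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(0, log(2))), c(1 / 3, 2 / 3))
  z <- c(-1.3, 0.2, 4.1)
  expect_equal(softmax(z + 17.5), softmax(z))
  expect_equal(sum(softmax(z * 100)), 1) # max-subtraction keeps large logits finite
  m <- softmax(rbind(z, z + 3))
  expect_equal(m[1, ], m[2, ])
  expect_error(softmax(numeric(0)), "empty")
})

test_that("head layouts follow the taxonomy shape", {
  tree <- makeShapedTaxonomy(c(3, 4, 9, 34, 57, 72, 1010),
                             levelNames = c("Kingdom", "Phylum", "Class", "Order",
                                            "Family", "Genus", "Species"))
  bb <- pixelBackbone(4)
  ml <- buildClassifier(bb, layoutFromTree(tree, "multilevel"), tree)
  expect_length(ml@heads, 7L)
  expect_identical(ncol(ml@heads[[7]]$W), 1010L) # Species head
  expect_identical(ncol(ml@heads[[5]]$W), 57L)   # Family head
  flat <- buildClassifier(bb, layoutFromTree(tree, "flat"), tree)
  expect_length(flat@heads, 1L)
  expect_identical(ncol(flat@heads[[1]]$W), 1010L)
  # taxonomy/layout mismatch is a configuration error
  expect_error(buildClassifier(bb, headLayout("multilevel", c(3, 4)), tree),
               "does not match")
})

test_that("every forward pass yields per-level probability vectors", {
  tree <- makeSyntheticTaxonomy(c(3, 2))
  bb <- pixelBackbone(6)
  mod <- buildClassifier(bb, layoutFromTree(tree), tree)
  imgs <- withr::with_seed(8, lapply(1:5, function(i) array(runif(6 * 6 * 3), c(6, 6, 3))))
  p <- predictImages(mod, imgs)
  expect_s4_class(p, "PredictionSet")
  for (l in 1:2) {
    expect_true(all(p@probs[[l]] >= 0))
    expect_equal(rowSums(p@probs[[l]]), rep(1, 5), tolerance = 1e-6)
  }
  expect_identical(predict(mod, imgs)@probs, p@probs)
})

test_that("multilevel cross-entropy has the stated closed forms", {
  mk <- function(mats) new("PredictionSet", probs = mats,
                           levelNames = paste0("l", seq_along(mats)))
  perfect <- mk(list(matrix(c(1, 0), 1), matrix(c(0, 0, 1, 0), 1)))
  expect_equal(multilevelLoss(perfect, c(0L, 2L)), 0)
  unif <- mk(list(matrix(0.5, 1, 2), matrix(0.25, 1, 4)))
  expect_equal(multilevelLoss(unif, c(1L, 3L)), log(2) + log(4))
  # invariant to permuting levels
  unifR <- mk(list(matrix(0.25, 1, 4), matrix(0.5, 1, 2)))
  expect_equal(multilevelLoss(unifR, c(3L, 1L)), multilevelLoss(unif, c(1L, 3L)))
  expect_error(multilevelLoss(unif, c(2L, 3L)), "out of range")
})

test_that("early stopping halts after the configured patience", {
  # strictly increasing: never halts
  up <- earlyStopper(seq(0.1, 0.9, by = 0.1), patience = 3)
  expect_false(up$halted)
  expect_identical(up$bestIndex, 9L)
  # constant trace: halts after 10 non-improving tests following the first
  const <- earlyStopper(rep(0.5, 11), patience = 10)
  expect_true(const$halted)
  expect_identical(const$haltIndex, 11L)
  expect_identical(const$bestIndex, 1L)
  # single early peak
  tr <- c(0.1, 0.2, rep(0.1, 10))
  sc <- earlyStopper(tr, patience = 10)
  expect_true(sc$halted)
  expect_identical(sc$bestIndex, 2L)
  # minDelta turns small gains into non-improvements
  md <- earlyStopper(c(0.5, 0.5005, 0.501), patience = 2, minDelta = 0.01)
  expect_true(md$halted)
  expect_identical(md$bestIndex, 1L)
})

test_that("an Adam step on a fixed batch decreases the multilevel loss", {
  tree <- makeSyntheticTaxonomy(c(2, 2))
  bb <- pixelBackbone(4)
  mod <- buildClassifier(bb, layoutFromTree(tree), tree, seed = 2)
  X <- withr::with_seed(3, matrix(rnorm(6 * bb@featureDim), 6))
  truth <- cbind(rep(0:1, 3), rep(0:3, length.out = 6))
  lossAt <- function(heads) {
    mod@heads <- heads
    multilevelLoss(predictImages(mod, X), truth)
  }
  Y <- list(truth[, 1], truth[, 2])
  fit <- rankvision:::trainHeads(mod@heads, X, Y, X, Y,
                                 trainConfig(learningRate = 1e-3, batchSize = 6,
                                             testIntervalEpochs = 1,
                                             patienceTests = 0, maxEpochs = 1))
  expect_lt(lossAt(fit$lastHeads), lossAt(mod@heads))
})

test_that("training is deterministic and reaches both-level perfection on clean data", {
  m <- clean_dataset()
  fit1 <- train_quick(m, seed = 7)
  fit2 <- train_quick(m, seed = 7)
  expect_identical(fit1$log, fit2$log)
  final <- fit1$log[fit1$log$test_index == max(fit1$log$test_index), ]
  expect_identical(final$top1, rep(1, 2))
  # patience 0: exactly one evaluation, first checkpoint returned
  bb <- tinyBackbone(32, 64, seed = 7)
  mod <- buildClassifier(bb, layoutFromTree(taxonomy(m)), taxonomy(m))
  one <- trainModel(mod, m, trainConfig(learningRate = 0.05, patienceTests = 0,
                                        testIntervalEpochs = 10, maxEpochs = 100))
  expect_identical(length(one$trace), 1L)
})

test_that("a single-level multilevel model matches the flat model exactly", {
  m <- clean_dataset()
  # collapse the taxonomy to its finest level only
  df <- records(m)
  tree1 <- buildTaxonomy(data.frame(s = taxonomy(m)@names[[2]]), "Species")
  df1 <- df[, c("path", "split")]
  df1$label_level0 <- df$label_level1
  m1 <- DatasetManifest(df1, tree1, m@imageRoot)
  bb <- tinyBackbone(32, 64, seed = 3)
  cfg <- trainConfig(learningRate = 0.05, maxEpochs = 60, seed = 5)
  fitML <- trainModel(buildClassifier(bb, layoutFromTree(tree1, "multilevel"), tree1),
                      m1, cfg)
  fitFlat <- trainModel(buildClassifier(bb, layoutFromTree(tree1, "flat"), tree1),
                        m1, cfg)
  expect_identical(fitML$log$top1, fitFlat$log$top1)
  expect_equal(fitML$model@heads, fitFlat$model@heads)
})

test_that("empty splits fail before any training", {
  m <- clean_dataset()
  df <- records(m)
  trainOnly <- DatasetManifest(df[df$split == "train", ], taxonomy(m), m@imageRoot)
  bb <- tinyBackbone(32, 16)
  mod <- buildClassifier(bb, layoutFromTree(taxonomy(m)), taxonomy(m))
  expect_error(trainModel(mod, trainOnly, trainConfig()), "empty test split")
})

test_that("checkpoints are self-describing round trips", {
  m <- clean_dataset()
  fit <- train_quick(m, maxEpochs = 20)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(fit$model, taxonomy(m), trainConfig(), f)
  back <- loadCheckpoint(f)
  expect_equal(back$model@heads, fit$model@heads)
  expect_identical(levelSizes(back$tree), levelSizes(taxonomy(m)))
})
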