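test_that("boostCombine reproduces the weighted-sum arithmetic", {
  mk <- function(v) new("PredictionSet", probs = list(matrix(v, 1)), levelNames = "s")
  # two members, y1=[0.6,0.4], y2=[0.2,0.8], w=[0.5,0.9] -> scores [0.48,0.92]
  comb <- boostCombine(list(mk(c(0.6, 0.4)), mk(c(0.2, 0.8))), c(0.5, 0.9))
  expect_equal(comb@probs[[1]][1, ], c(0.48, 0.92) / 1.4)
  expect_identical(which.max(comb@probs[[1]][1, ]), 2L)
  # a single member is unchanged after renormalisation
  single <- boostCombine(list(mk(c(0.6, 0.4))), 0.7)
  expect_equal(single@probs[[1]][1, ], c(0.6, 0.4))
})

test_that("boostCombine is idempotent on identical members and sums to 1", {
  p <- random_predset(20, c(3, 6), seed = 4)
  same <- boostCombine(list(p, p, p), c(0.5, 0.5, 0.5))
  expect_equal(same@probs, p@probs)
  w <- matrix(c(0.3, 0.9, 0.5, 0.4), 2, 2)
  q <- random_predset(20, c(3, 6), seed = 5)
  comb <- boostCombine(list(p, q), w)
  for (l in 1:2) expect_equal(rowSums(comb@probs[[l]]), rep(1, 20))
})

test_that("boostCombine equals a brute-force oracle on random inputs", {
  for (seed in 1:3) {
    members <- lapply(1:3, function(m) random_predset(15, c(2, 5), seed = seed * 10 + m))
    w <- withr::with_seed(seed, matrix(runif(6, 0.1, 1), 3, 2))
    comb <- boostCombine(members, w)
    expect_equal(comb@probs, oracle_boost(members, w))
  }
})

test_that("one-hot disagreeing members tie and break towards the lowest id", {
  mk <- function(i) new("PredictionSet",
                        probs = list(matrix(as.numeric(seq_len(3) == i), 1)),
                        levelNames = "s")
  comb <- boostCombine(list(mk(2), mk(3)), c(1, 1))
  expect_equal(comb@probs[[1]][1, ], c(0, 0.5, 0.5))
  # deterministic tie-break: lowest id among the tied classes
  expect_identical(max.col(comb@probs[[1]], ties.method = "first"), 2L)
  expect_error(boostCombine(list(mk(1), mk(2)), c(0, 0)), "positive weight")
})

test_that("stacking identity-initialisation reproduces a single member", {
  p <- random_predset(12, c(2, 4), seed = 6)
  truth <- withr::with_seed(6, cbind(sample(0:1, 12, TRUE), sample(0:3, 12, TRUE)))
  stack <- fitStacking(list(p), truth, trainConfig(maxEpochs = 0), identityInit = TRUE)
  out <- stackCombine(stack, list(p))
  expect_equal(out@probs, p@probs, tolerance = 1e-9)
  # meta-layer input width = sum over members and levels of level sizes
  expect_identical(nrow(stack@heads[[1]]$W), 6L)
  p2 <- random_predset(12, c(2, 4), seed = 7)
  stack2 <- fitStacking(list(p, p2), truth, trainConfig(maxEpochs = 0))
  expect_identical(nrow(stack2@heads[[1]]$W), 12L)
  expect_error(stackCombine(stack2, list(p)), "fitted on 2 members")
})

test_that("the trained stack tracks the reliable member on a separable stream", {
  n <- 120
  truth <- cbind(rep(0:1, n / 2))
  p <- 0.1 + 0.8 * truth[, 1]
  good <- new("PredictionSet", probs = list(cbind(1 - p, p)), levelNames = "s")
  bad <- new("PredictionSet", probs = list(cbind(p, 1 - p)), levelNames = "s")
  stack <- fitStacking(list(bad, good), truth,
                       trainConfig(learningRate = 0.1, batchSize = 32,
                                   testIntervalEpochs = 5, patienceTests = 5,
                                   maxEpochs = 100, seed = 2))
  out <- stackCombine(stack, list(bad, good))
  accStack <- oracle_topk(out@probs[[1]], truth[, 1], 1)
  accGood <- oracle_topk(good@probs[[1]], truth[, 1], 1)
  expect_gte(accStack, accGood - 0.02)
})

test_that("boosting two members with disjoint confident errors beats both", {
  # member 1 errs on odd samples, member 2 on even ones; errors are confident
  # but the correct member is always more confident elsewhere
  n <- 40
  y <- rep(0:1, n / 2)
  conf <- function(right, wrongIdx) {
    P <- cbind(1 - y, y) * 0.98 + 0.01
    P[wrongIdx, ] <- P[wrongIdx, 2:1] * 0.7 + 0.15
    P / rowSums(P)
  }
  m1 <- new("PredictionSet", probs = list(conf(y, seq(1, n, 4))), levelNames = "s")
  m2 <- new("PredictionSet", probs = list(conf(y, seq(3, n, 4))), levelNames = "s")
  acc1 <- oracle_topk(m1@probs[[1]], y, 1)
  acc2 <- oracle_topk(m2@probs[[1]], y, 1)
  comb <- boostCombine(list(m1, m2), c(acc1, acc2))
  accE <- oracle_topk(comb@probs[[1]], y, 1)
  expect_gt(accE, acc1)
  expect_gt(accE, acc2)
})

test_that("cascadeLayout partitions the finer levels by routed subtree", {
  tree <- makeShapedTaxonomy(c(3, 4, 9, 34, 57, 72, 1010))
  lay <- cascadeLayout(tree, 2L)
  expect_identical(lay$nSpecialists, 4L)
  # the subtree species spaces partition all 1010 species
  species <- sort(unlist(lapply(lay$localToGlobal, function(x) x[[5]])))
  expect_identical(species, 0:1009)
  # degenerate single-category routing level
  chain <- makeSyntheticTaxonomy(c(1, 4))
  expect_identical(cascadeLayout(chain, 1L)$nSpecialists, 1L)
})

test_that("a trained cascade restricts mass to the routed subtree", {
  m <- clean_dataset()
  bb <- tinyBackbone(32, 64, seed = 2)
  cfg <- trainConfig(learningRate = 0.05, batchSize = 16, testIntervalEpochs = 10,
                     patienceTests = 5, maxEpochs = 120, seed = 2)
  cascade <- buildCascade(m, 1L, bb, cfg)
  expect_length(cascade@specialists, 2L)
  # each specialist was trained on exactly half the training records
  df <- records(m)
  expect_identical(sum(df$split == "train" & df$label_level0 == 0), 16L)
  te <- df[df$split == "test", ]
  X <- backboneFeatures(bb, te, m@imageRoot)
  pred <- cascadePredict(cascade, X)
  routed <- max.col(pred@probs[[1]], ties.method = "first") - 1L
  for (i in seq_len(nrow(te))) {
    inSubtree <- cascade@localToGlobal[[routed[i] + 1]][[1]] + 1L
    expect_identical(sum(pred@probs[[2]][i, -inSubtree]), 0)
  }
  # noiseless data: router and specialists are perfect, so leaf top-1 is 1
  truth <- labelsMatrix(m, "test")
  expect_identical(topkAccuracy(pred, truth, 1, 2), 1)
  expect_identical(topkAccuracy(pred, truth, 1, 1), 1)
})

test_that("cascade error equals routing error when specialists are perfect", {
  m <- clean_dataset()
  bb <- tinyBackbone(32, 64, seed = 2)
  cfg <- trainConfig(learningRate = 0.05, batchSize = 16, testIntervalEpochs = 10,
                     patienceTests = 5, maxEpochs = 120, seed = 2)
  cascade <- buildCascade(m, 1L, bb, cfg)
  te <- records(m)[records(m)$split == "test", ]
  truth <- labelsMatrix(m, "test")
  X <- backboneFeatures(bb, te, m@imageRoot)
  # force routing mistakes on a chosen subset
  n <- nrow(te)
  wrong <- c(1, 4, 7)
  routing <- matrix(0, n, 2)
  routing[cbind(seq_len(n), truth[, 1] + 1)] <- 1
  routing[wrong, ] <- routing[wrong, 2:1]
  pred <- cascadePredict(cascade, X, routingProbs = routing)
  a <- 1 - length(wrong) / n
  expect_equal(topkAccuracy(pred, truth, 1, 1), a)
  # leaf accuracy cannot exceed (and here equals) the routing accuracy
  expect_equal(topkAccuracy(pred, truth, 1, 2), a)
})

test_that("a missing routing category aborts cascade training by name", {
  m <- clean_dataset()
  df <- records(m)
  df <- df[!(df$split == "train" & df$label_level0 == 1), ]
  m2 <- DatasetManifest(df, taxonomy(m), m@imageRoot)
  expect_error(buildCascade(m2, 1L, tinyBackbone(32, 16), trainConfig(maxEpochs = 10)),
               "has no training records")
})
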