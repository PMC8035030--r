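test_that("top-k accuracy matches closed forms and the brute-force oracle", {
  # perfect one-hot predictions
  n <- 8; K <- 5
  y <- rep(0:(K - 1), length.out = n)
  P <- matrix(0, n, K); P[cbind(1:n, y + 1)] <- 1
  pred <- new("PredictionSet", probs = list(P), levelNames = "s")
  expect_identical(topkAccuracy(pred, y, 1), 1)
  expect_identical(topkAccuracy(pred, y, 5), 1)
  # k = level size is always 1
  r <- random_predset(30, K, seed = 1)
  expect_identical(topkAccuracy(r, withr::with_seed(2, sample(0:(K - 1), 30, TRUE)), K), 1)
  # uniform predictions with the lowest-id tie-break: enumerate all truths
  U <- new("PredictionSet", probs = list(matrix(1 / K, K, K)), levelNames = "s")
  for (k in 1:K)
    expect_equal(topkAccuracy(U, 0:(K - 1), k), k / K)
  expect_error(topkAccuracy(r, rep(0L, 30), 0), "k must be")
  expect_error(topkAccuracy(r, rep(0L, 30), 6), "k must be")
})

test_that("per-class F1 matches the confusion-count definition", {
  # class 0: TP=1, FP=1, FN=1 -> F1 = 0.5
  P <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.3, 0.7))
  y <- c(0, 1, 0, 1)
  pred <- new("PredictionSet", probs = list(P), levelNames = "s")
  res <- perClassF1(pred, y)
  expect_equal(res$perClass$f1[1], 0.5)
  # perfect predictions: all F1 = 1
  I <- matrix(0, 4, 2); I[cbind(1:4, y + 1)] <- 1
  perf <- perClassF1(new("PredictionSet", probs = list(I), levelNames = "s"), y)
  expect_equal(perf$perClass$f1, c(1, 1))
  expect_equal(perf$weightedF1, 1)
  expect_error(perClassF1(new("PredictionSet",
                              probs = list(matrix(numeric(0), 0, 2)),
                              levelNames = "s"), integer(0)), "empty")
})

test_that("weighted F1 is invariant under class relabelling", {
  K <- 4
  p <- random_predset(60, K, seed = 3)
  y <- withr::with_seed(4, sample(0:(K - 1), 60, TRUE))
  base <- perClassF1(p, y)$weightedF1
  perm <- withr::with_seed(5, sample(0:(K - 1)))
  pPerm <- new("PredictionSet", probs = list(p@probs[[1]][, perm + 1]),
               levelNames = "s")
  yPerm <- match(y, perm) - 1L
  expect_equal(perClassF1(pPerm, yPerm)$weightedF1, base)
})

test_that("the F1 normal fit follows its closed forms and conventions", {
  allEq <- fitF1Normal(rep(0.7, 10))
  expect_equal(allEq[["sigma"]], 0)
  expect_equal(allEq[["within1"]], 1)
  expect_equal(allEq[["within2"]], 1)
  two <- fitF1Normal(c(0.5, 0.7))
  expect_equal(two[["mu"]], 0.6)
  expect_equal(two[["sigma"]], 0.1)             # population convention
  expect_equal(fitF1Normal(c(0.5, 0.7), sample = TRUE)[["sigma"]],
               sqrt(0.02), tolerance = 1e-12)   # ~0.1414 with n-1
  expect_error(fitF1Normal(0.5), "at least 2")
})

test_that("the normal fit recovers parameters from N(0.60, 0.04) at n = 1010", {
  draws <- withr::with_seed(10, rnorm(1010, 0.60, 0.04))
  fit <- fitF1Normal(draws)
  expect_lt(abs(fit[["mu"]] - 0.60), 3 * 0.04 / sqrt(1010))
  expect_lt(abs(fit[["sigma"]] - 0.04) / 0.04, 0.10)
  expect_lt(abs(fit[["within1"]] - 0.683), 0.05)
  expect_lt(abs(fit[["within2"]] - 0.954), 0.03)
})

test_that("AUC matches rank-pair counting, including ties and edge cases", {
  # 2-class toy: scores [0.9, 0.8, 0.3], truths [1, 0, 1]: one concordant,
  # one discordant pair -> 0.5
  P <- cbind(1 - c(0.9, 0.8, 0.3), c(0.9, 0.8, 0.3))
  pred <- new("PredictionSet", probs = list(P), levelNames = "s")
  expect_equal(aucScore(pred, c(1, 0, 1)), oracle_macro_auc(P, c(1, 0, 1)))
  expect_equal(oracle_auc_binary(c(0.9, 0.8, 0.3), c(TRUE, FALSE, TRUE)), 0.5)
  # perfect ranking
  Pp <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(aucScore(new("PredictionSet", probs = list(Pp), levelNames = "s"),
                        c(0, 0, 1, 1)), 1)
  # constant scores are uninformative
  Pc <- matrix(0.5, 6, 2)
  expect_equal(aucScore(new("PredictionSet", probs = list(Pc), levelNames = "s"),
                        rep(0:1, 3)), 0.5)
  expect_error(aucScore(new("PredictionSet", probs = list(matrix(1, 3, 1)),
                            levelNames = "s"), rep(0, 3)), "single-class")
})

test_that("all metrics equal independent brute-force oracles on a 200-sample fixture", {
  n <- 200; sizes <- c(3, 10)
  pred <- random_predset(n, sizes, seed = 21)
  truth <- withr::with_seed(22, cbind(sample(0:2, n, TRUE), sample(0:9, n, TRUE)))
  for (l in 1:2) {
    P <- pred@probs[[l]]
    for (k in c(1, 3)) {
      expect_equal(topkAccuracy(pred, truth, k, l), oracle_topk(P, truth[, l], k))
    }
    o <- oracle_f1(P, truth[, l])
    got <- perClassF1(pred, truth, l)
    expect_equal(got$perClass$f1, o$f1)
    expect_equal(got$weightedF1, o$weighted)
    expect_equal(aucScore(pred, truth, l), oracle_macro_auc(P, truth[, l]))
  }
  # cross-check the binary AUC machinery against pROC
  skip_if_not_installed("pROC")
  y <- truth[, 1] == 0
  proc <- as.numeric(pROC::auc(pROC::roc(y, pred@probs[[1]][, 1], quiet = TRUE,
                                         direction = "<")))
  expect_equal(rankvision:::binaryAUC(pred@probs[[1]][, 1], y), proc)
})

test_that("evaluateModel assembles a coherent report and top-5 >= top-1", {
  pred <- random_predset(80, c(2, 6), seed = 30)
  truth <- withr::with_seed(31, cbind(sample(0:1, 80, TRUE), sample(0:5, 80, TRUE)))
  rep <- evaluateModel(pred, truth)
  expect_s4_class(rep, "EvalReport")
  expect_identical(nrow(rep@perLevel), 2L)
  expect_true(all(rep@perLevel$top5 >= rep@perLevel$top1))
  expect_true(rep@weightedF1 >= 0 && rep@weightedF1 <= 1)
  expect_gte(rep@f1Normal[["sigma"]], 0)
  # report files parse back
  stem <- file.path(withr::local_tempdir(), "r")
  writeEvalReport(rep, stem)
  js <- jsonlite::fromJSON(paste0(stem, ".json"))
  expect_equal(js$weightedF1, rep@weightedF1)
  lv <- read.csv(paste0(stem, "_levels.csv"))
  expect_identical(nrow(lv), 2L)
})
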