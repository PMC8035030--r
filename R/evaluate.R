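# Per-rank evaluation protocol: top-k accuracy, per-class F1 and its
# support-weighted mean, macro one-vs-rest ROC AUC, and a normal fit to the
# per-class F1 distribution.

argmaxIds <- function(P) max.col(P, ties.method = "first") - 1L

#' Top-k accuracy at one taxonomy level
#'
#' Fraction of samples whose true category is among the `k` highest-
#' probability categories; ties inside the top-k boundary are resolved
#' deterministically towards the lowest category id.
#'
#' @param pred a [PredictionSet-class].
#' @param truth integer matrix (samples x levels) or vector of 0-based ids.
#' @param k number of guesses.
#' @param level 1-based level index.
#' @return accuracy in `[0,1]`.
#' @export
topkAccuracy <- function(pred, truth, k = 1L, level = nLevels(pred)) {
  if (!is.matrix(truth)) truth <- matrix(truth, ncol = nLevels(pred))
  P <- pred@probs[[level]]
  if (k < 1L || k > ncol(P))
    stopf("k must be in 1..%d, got %s", ncol(P), k)
  topkFromProbs(P, truth[, level], k)
}

#' Per-class precision, recall and F1 at one level
#'
#' One-vs-rest counts from argmax decisions. The weighted F1 is the
#' support-weighted mean over classes with nonzero support.
#'
#' @param pred a [PredictionSet-class].
#' @param truth integer matrix or vector of 0-based true ids.
#' @param level 1-based level index (default: finest).
#' @return list with `perClass` (data.frame: class, precision, recall, f1,
#'   support) and `weightedF1`.
#' @export
perClassF1 <- function(pred, truth, level = nLevels(pred)) {
  if (!is.matrix(truth)) truth <- matrix(truth, ncol = nLevels(pred))
  y <- truth[, level]
  if (length(y) == 0L) stopf("perClassF1: empty input")
  P <- pred@probs[[level]]
  yhat <- argmaxIds(P)
  K <- ncol(P)
  tp <- fp <- fn <- numeric(K)
  for (c in seq_len(K) - 1L) {
    tp[c + 1L] <- sum(y == c & yhat == c)
    fp[c + 1L] <- sum(y != c & yhat == c)
    fn[c + 1L] <- sum(y == c & yhat != c)
  }
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- tabulate(y + 1L, nbins = K)
  keep <- support > 0L
  list(perClass = data.frame(class = seq_len(K) - 1L, precision = prec,
                             recall = rec, f1 = f1, support = support),
       weightedF1 = sum(f1[keep] * support[keep]) / sum(support[keep]))
}

#' Normal fit to a per-class F1 distribution
#'
#' Fits mean and standard deviation to the per-class F1 scores and reports
#' the empirical fraction of classes within one and two standard deviations
#' of the mean. The population standard deviation (divide by n) is the
#' default, matching the descriptive use of the fit; set `sample = TRUE` for
#' the n-1 convention.
#'
#' @param f1 numeric vector of per-class F1 scores (length >= 2).
#' @param sample use the sample (n-1) standard deviation.
#' @return named numeric: `mu`, `sigma`, `within1`, `within2`.
#' @export
fitF1Normal <- function(f1, sample = FALSE) {
  n <- length(f1)
  if (n < 2L) stopf("fitF1Normal needs at least 2 classes")
  mu <- mean(f1)
  sigma <- sqrt(sum((f1 - mu)^2) / (if (sample) n - 1L else n))
  c(mu = mu, sigma = sigma,
    within1 = mean(f1 >= mu - sigma & f1 <= mu + sigma),
    within2 = mean(f1 >= mu - 2 * sigma & f1 <= mu + 2 * sigma))
}

# one-vs-rest AUC via the rank-sum statistic (ties get average ranks)
binaryAUC <- function(score, pos) {
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Macro one-vs-rest ROC AUC at one level
#'
#' Averages the one-vs-rest AUC over every class with at least one positive
#' and one negative sample.
#'
#' @param pred a [PredictionSet-class].
#' @param truth integer matrix or vector of 0-based true ids.
#' @param level 1-based level index (default: finest).
#' @return macro AUC in `[0,1]`.
#' @export
aucScore <- function(pred, truth, level = nLevels(pred)) {
  if (!is.matrix(truth)) truth <- matrix(truth, ncol = nLevels(pred))
  y <- truth[, level]
  P <- pred@probs[[level]]
  if (ncol(P) < 2L) stopf("AUC undefined for a single-class level")
  aucs <- vapply(seq_len(ncol(P)) - 1L,
                 function(c) binaryAUC(P[, c + 1L], y == c), 1)
  aucs <- aucs[!is.na(aucs)]
  if (length(aucs) == 0L) stopf("AUC undefined: no class has both positives and negatives")
  mean(aucs)
}

#' Full per-rank evaluation
#'
#' @param pred a [PredictionSet-class].
#' @param truth integer matrix (samples x levels) of 0-based true ids.
#' @param topK top-k cutoff in addition to top-1 (capped at the level size).
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(pred, truth, topK = 5L) {
  if (!is.matrix(truth)) truth <- matrix(truth, ncol = nLevels(pred))
  L <- nLevels(pred)
  rows <- lapply(seq_len(L), function(l) {
    P <- pred@probs[[l]]
    data.frame(level = pred@levelNames[l],
               top1 = topkAccuracy(pred, truth, 1L, l),
               top5 = topkAccuracy(pred, truth, min(topK, ncol(P)), l),
               loss = mean(-log(pmax(P[cbind(seq_len(nrow(P)), truth[, l] + 1L)],
                                     1e-12))),
               stringsAsFactors = FALSE)
  })
  pc <- perClassF1(pred, truth, L)
  auc <- if (ncol(pred@probs[[L]]) >= 2L) aucScore(pred, truth, L) else NA_real_
  present <- pc$perClass$support > 0
  fn <- if (sum(present) >= 2L) fitF1Normal(pc$perClass$f1[present])
        else c(mu = NA_real_, sigma = NA_real_, within1 = NA_real_, within2 = NA_real_)
  new("EvalReport", perLevel = do.call(rbind, rows), perClass = pc$perClass,
      weightedF1 = pc$weightedF1, auc = auc, f1Normal = fn)
}

#' Write an evaluation report to JSON and CSV
#'
#' Emits `<stem>.json` (full report), `<stem>_levels.csv` (one row per
#' level) and `<stem>_classes.csv` (finest-level per-class metrics).
#'
#' @param report an [EvalReport-class].
#' @param stem output path stem.
#' @return character vector of the written paths, invisibly.
#' @export
writeEvalReport <- function(report, stem) {
  paths <- c(json = paste0(stem, ".json"),
             levels = paste0(stem, "_levels.csv"),
             classes = paste0(stem, "_classes.csv"))
  doc <- list(perLevel = report@perLevel,
              weightedF1 = report@weightedF1, auc = report@auc,
              f1Normal = as.list(report@f1Normal))
  jsonlite::write_json(doc, paths["json"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(report@perLevel, paths["levels"], row.names = FALSE)
  utils::write.csv(report@perClass, paths["classes"], row.names = FALSE)
  invisible(paths)
}
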