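# Binary-classification metrics (ACC, Sn, Sp, MCC, AUC) and the stratified
# cross-validation harness used throughout the stacking pipeline.

#' Confusion counts at a probability threshold
#'
#' A sample is called positive when its score is strictly greater than
#' `threshold` (the convention used for both the class meta-features and the
#' final label).
#'
#' @param labels 0/1 vector of true labels.
#' @param scores Numeric vector of probabilities/scores, same length.
#' @param threshold Decision threshold (default 0.5, strict `>`).
#' @return One-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    stop("`labels` and `scores` must have the same length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  pred <- as.integer(scores > threshold)
  tibble::tibble(
    tp = sum(pred == 1 & labels == 1),
    tn = sum(pred == 0 & labels == 0),
    fp = sum(pred == 1 & labels == 0),
    fn = sum(pred == 0 & labels == 1)
  )
}

#' Accuracy, sensitivity, specificity and MCC from confusion counts
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A zero
#' factor in the MCC denominator yields MCC = 0 (the usual convention); a
#' zero Sn or Sp denominator is an error (it cannot occur when both classes
#' are present).
#'
#' @param counts One-row data frame / list with `tp`, `tn`, `fp`, `fn`.
#' @return One-row tibble with `acc`, `sn`, `sp`, `mcc`.
#' @export
metrics_from_confusion <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("sensitivity/specificity undefined: a class is absent", call. = FALSE)
  }
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  tibble::tibble(
    acc = (tp + tn) / n,
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    mcc = mcc
  )
}

#' Rank-based AUC (Mann-Whitney with midrank ties)
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Numeric scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("`labels` and `scores` must have the same length", call. = FALSE)
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric set for scored predictions
#'
#' @inheritParams confusion
#' @return One-row tibble with `acc`, `sn`, `sp`, `mcc`, `auc`, `n`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  m <- metrics_from_confusion(confusion(labels, scores, threshold))
  m$auc <- auc_score(labels, scores)
  m$n <- length(labels)
  m
}

#' ROC curve points
#'
#' Threshold sweep over the observed scores; suitable for plotting or
#' trapezoidal integration.
#'
#' @inheritParams auc_score
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, sorted by
#'   increasing `fpr`.
#' @export
roc_points <- function(labels, scores) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 0)
  tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Stratified fold assignment
#'
#' Shuffles each class independently (seeded) and deals indices round-robin,
#' so per-fold class counts differ from perfect proportionality by at most
#' one sample.
#'
#' @param labels 0/1 vector; each class must have at least `folds` members.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return Integer vector of fold ids in `1..folds`, aligned to `labels`.
#' @export
stratified_folds <- function(labels, folds = 10, seed = 1) {
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < folds)) {
    stop("each class needs at least `folds` samples; reduce `folds` ",
         "(class counts: ", paste(counts, collapse = "/"), ")", call. = FALSE)
  }
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Stratified cross-validation with pooled out-of-fold predictions
#'
#' Fits `model_factory` on each training fold and scores the held-out fold;
#' all out-of-fold scores are pooled and one metric set is computed on the
#' pooled predictions (threshold-consistent with an independent test).
#'
#' @param model_factory `function(x_train, y_train)` returning a
#'   `function(x_test)` that yields probabilities of the positive class.
#' @param features Numeric matrix or feature tibble (id column allowed).
#' @param labels 0/1 vector aligned to rows.
#' @param folds,seed Passed to [stratified_folds()].
#' @return List with `metrics` (one-row tibble), `scores` (pooled
#'   out-of-fold probabilities) and `fold` (fold assignment).
#' @export
crossvalidate <- function(model_factory, features, labels, folds = 10, seed = 1) {
  x <- if (is.data.frame(features)) feature_matrix(features) else features
  if (nrow(x) != length(labels)) stop("features/labels misaligned", call. = FALSE)
  fold <- stratified_folds(labels, folds, seed)
  scores <- numeric(length(labels))
  for (f in seq_len(folds)) {
    tr <- fold != f
    predictor <- model_factory(x[tr, , drop = FALSE], labels[tr])
    scores[!tr] <- predictor(x[!tr, , drop = FALSE])
  }
  list(metrics = classification_metrics(labels, scores),
       scores = scores, fold = fold)
}

#' Round metrics for reporting
#'
#' Three decimals, round-half-even (the precision used in result tables).
#'
#' @param metrics Tibble of numeric metric columns.
#' @return Tibble with numeric columns rounded to 3 decimals.
#' @export
round_metrics <- function(metrics) {
  dplyr::mutate(metrics, dplyr::across(dplyr::where(is.numeric),
                                       ~ round(.x, 3)))
}
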