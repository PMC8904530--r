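# Stacked generalization: probabilistic meta-features from the baseline pool,
# two-step feature selection (gradient-boosting importance ranking + top-k
# subset sweep by cross-validated MCC) and the random-forest meta-model.

meta_kind <- function(meta) attr(meta, "kind") %||% "PF"

new_meta_matrix <- function(values, ids, kind, fold = NULL) {
  tbl <- dplyr::bind_cols(tibble::tibble(id = ids),
                          tibble::as_tibble(as.data.frame(values,
                                                          check.names = FALSE)))
  attr(tbl, "kind") <- kind
  if (!is.null(fold)) attr(tbl, "fold") <- fold
  tbl
}

#' Generate probabilistic meta-features (PF) on the training set
#'
#' Column m holds baseline member m's probability of the positive class for
#' every training sample. By default these are out-of-fold: within each
#' stratified fold the member's (descriptor, algorithm, chosen parameters)
#' configuration is refit on the remaining folds and scores only the held-out
#' samples, so no sample's meta-feature comes from a model that saw it.
#' `mode = "in-sample"` instead scores all samples with the fully fitted pool
#' members (useful only for protocol comparisons; it leaks).
#'
#' @param pool A `baseline_pool` from [train_pool()].
#' @param features_by_descriptor Named list of feature tibbles covering the
#'   pool's descriptors, row-aligned to `labels`.
#' @param labels 0/1 training labels.
#' @param folds,seed Fold controls (default: the pool's own settings).
#' @param mode `"out-of-fold"` (default) or `"in-sample"`.
#' @return Tibble (`id` + one column per member, values in `[0, 1]`) with
#'   attributes `kind = "PF"` and `fold` (the assignment used).
#' @export
generate_pf <- function(pool, features_by_descriptor, labels,
                        folds = NULL, seed = NULL,
                        mode = c("out-of-fold", "in-sample")) {
  mode <- match.arg(mode)
  folds <- folds %||% pool$folds
  seed <- seed %||% pool$seed
  ids <- features_by_descriptor[[1]]$id
  if (length(ids) != length(labels)) stop("features/labels misaligned",
                                          call. = FALSE)
  missing <- setdiff(pool$descriptors, names(features_by_descriptor))
  if (length(missing)) stop("missing descriptor matrix: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  mats <- lapply(features_by_descriptor, feature_matrix)
  labels <- as.numeric(labels)
  fold <- stratified_folds(labels, folds, seed)
  out <- matrix(NA_real_, length(labels), length(pool$members),
                dimnames = list(NULL, names(pool$members)))
  for (m in names(pool$members)) {
    member <- pool$members[[m]]
    x <- mats[[member$spec$descriptor]]
    if (mode == "in-sample") {
      out[, m] <- predict_baseline(member, x)
    } else {
      for (f in seq_len(folds)) {
        tr <- fold != f
        if (length(unique(labels[tr])) < 2 || length(unique(labels[!tr])) < 1) {
          stop("a fold lost a class; use fewer folds", call. = FALSE)
        }
        clf <- make_classifier(member$spec$algorithm, member$chosen_params,
                               seed = member$spec$seed + f)
        clf <- fit_classifier(clf, x[tr, , drop = FALSE], labels[tr])
        out[!tr, m] <- predict_prob(clf, x[!tr, , drop = FALSE])
      }
    }
  }
  new_meta_matrix(out, ids, "PF", fold)
}

#' Probabilistic meta-features for new (test) data
#'
#' Scores new samples with the pool members as fitted on the full training
#' set; deterministic, no refitting.
#'
#' @inheritParams generate_pf
#' @return Tibble with `kind = "PF"`, one column per member.
#' @export
pf_for_new_data <- function(pool, features_by_descriptor) {
  missing <- setdiff(pool$descriptors, names(features_by_descriptor))
  if (length(missing)) stop("missing descriptor matrix: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  ids <- features_by_descriptor[[1]]$id
  mats <- lapply(features_by_descriptor, feature_matrix)
  out <- vapply(names(pool$members), function(m) {
    member <- pool$members[[m]]
    predict_baseline(member, mats[[member$spec$descriptor]])
  }, numeric(length(ids)))
  if (length(ids) == 1) out <- matrix(out, 1, dimnames = list(NULL, names(pool$members)))
  new_meta_matrix(out, ids, "PF")
}

#' Class meta-features (CF): thresholded PF
#'
#' An entry is 1 when the probability is strictly greater than 0.5,
#' otherwise 0.
#'
#' @param pf A PF tibble from [generate_pf()] / [pf_for_new_data()].
#' @return Tibble of 0/1 values with `kind = "CF"`.
#' @export
binarize_cf <- function(pf) {
  stopifnot(meta_kind(pf) == "PF")
  vals <- feature_matrix(pf)
  new_meta_matrix((vals > 0.5) * 1, pf$id, "CF", attr(pf, "fold"))
}

#' Concatenated meta-features (PCF = [PF | CF])
#'
#' Column-binds the PF block (suffix `.PF`) and the CF block (suffix `.CF`).
#'
#' @param pf PF tibble; @param cf CF tibble, same rows and member columns.
#' @return Tibble with twice the member columns, `kind = "PCF"`.
#' @export
concat_pcf <- function(pf, cf) {
  stopifnot(meta_kind(pf) == "PF", meta_kind(cf) == "CF")
  mp <- feature_matrix(pf); mc <- feature_matrix(cf)
  if (!identical(dim(mp), dim(mc)) || !identical(pf$id, cf$id)) {
    stop("PF and CF are not aligned", call. = FALSE)
  }
  colnames(mp) <- paste0(colnames(mp), ".PF")
  colnames(mc) <- paste0(colnames(mc), ".CF")
  new_meta_matrix(cbind(mp, mc), pf$id, "PCF", attr(pf, "fold"))
}

#' Rank meta-feature columns by gradient-boosting importance
#'
#' Fits a gradient-boosted tree classifier on the meta-features and orders
#' columns by decreasing importance (gain); ties, and columns the booster
#' never used, fall back to ascending column index.
#'
#' @param meta Meta-feature tibble.
#' @param labels 0/1 labels.
#' @param seed Integer seed.
#' @param nrounds,max_depth Booster size.
#' @return Integer permutation of the column indices, most important first.
#' @export
rank_features <- function(meta, labels, seed = 1, nrounds = 100, max_depth = 3) {
  x <- feature_matrix(meta)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present",
                                       call. = FALSE)
  bst <- withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = 0.3, nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = labels, nthread = 1),
    nrounds = nrounds, verbose = 0))
  imp <- xgboost::xgb.importance(model = bst)
  gain <- stats::setNames(rep(0, ncol(x)), colnames(x))
  gain[imp$Feature] <- imp$Gain
  order(-gain, seq_len(ncol(x)))
}

#' Default tuning grid of the random-forest meta-model
#' @param reduced Single-point grid for fast runs.
#' @return List of parameter lists.
#' @export
meta_rf_grid <- function(reduced = FALSE) {
  if (reduced) return(list(list(num.trees = 300, mtry_rule = "sqrt")))
  pts <- expand.grid(num.trees = c(100, 300, 500),
                     mtry_rule = c("sqrt", "log2"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(pts)), function(i) as.list(pts[i, , drop = FALSE]))
}

#' Sweep top-k meta-feature subsets and pick the MCC-maximal one
#'
#' For each candidate size k (default top 5 to top 100 in steps of 5) the
#' random-forest meta-model is tuned over `rf_grid` and evaluated by pooled
#' out-of-fold MCC on the top-k ranked columns; the chosen subset is the MCC
#' maximiser, ties resolved towards the smallest k. Candidate sizes larger
#' than the number of columns are dropped with a warning.
#'
#' @param meta Meta-feature tibble (training, out-of-fold).
#' @param labels 0/1 labels.
#' @param ranking Column permutation from [rank_features()].
#' @param k_grid Candidate subset sizes.
#' @param folds,seed Cross-validation controls.
#' @param rf_grid Meta random-forest grid, see [meta_rf_grid()].
#' @return A `selection_result` with the ranking, the per-k MCC curve, the
#'   chosen size/columns and the winning meta-model parameters.
#' @export
sweep_subsets <- function(meta, labels, ranking, k_grid = seq(5, 100, 5),
                          folds = 10, seed = 1, rf_grid = meta_rf_grid()) {
  x <- feature_matrix(meta)
  labels <- as.numeric(labels)
  if (length(k_grid) == 0) stop("empty k_grid", call. = FALSE)
  valid <- k_grid[k_grid <= ncol(x)]
  if (length(valid) < length(k_grid)) {
    warning("dropping k_grid entries exceeding ", ncol(x), " columns")
  }
  if (length(valid) == 0) stop("no usable subset size in k_grid", call. = FALSE)
  fold <- stratified_folds(labels, folds, seed)
  eval_rf <- function(cols, params) {
    scores <- numeric(length(labels))
    for (f in seq_len(folds)) {
      tr <- fold != f
      clf <- make_classifier("RF", params, seed = seed + f)
      clf <- fit_classifier(clf, x[tr, cols, drop = FALSE], labels[tr])
      scores[!tr] <- predict_prob(clf, x[!tr, cols, drop = FALSE])
    }
    classification_metrics(labels, scores)
  }
  per_k <- purrr::map_dfr(valid, function(k) {
    cols <- ranking[seq_len(k)]
    evals <- lapply(rf_grid, function(p) eval_rf(cols, p))
    mccs <- vapply(evals, function(e) e$mcc, 0)
    best <- which.max(mccs)
    dplyr::bind_cols(tibble::tibble(k = k),
                     evals[[best]],
                     tibble::tibble(params = list(rf_grid[[best]])))
  })
  chosen_i <- which.max(per_k$mcc)  # first max -> smallest k on ties
  chosen_k <- per_k$k[chosen_i]
  structure(list(
    ranking = ranking,
    k_grid = valid,
    per_k = per_k,
    chosen_k = chosen_k,
    chosen_columns = colnames(x)[ranking[seq_len(chosen_k)]],
    meta_params = per_k$params[[chosen_i]],
    kind = meta_kind(meta)
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> kind ", x$kind, ": chose top-", x$chosen_k,
      " of ", length(x$ranking), " columns (cv MCC ",
      round(x$per_k$mcc[x$per_k$k == x$chosen_k], 3), ")\n", sep = "")
  invisible(x)
}

#' Fit the stacked model (random-forest meta-model on selected PFs)
#'
#' @param pool The fitted `baseline_pool`.
#' @param meta Training meta-feature tibble of the selected kind.
#' @param labels 0/1 labels.
#' @param selection A `selection_result` computed on `meta`.
#' @param seed Seed for the meta-model fit.
#' @return A `scorpion_model` carrying the pool, the selection and the fitted
#'   meta-model; decision threshold 0.5 (strict `>`).
#' @export
fit_stacked <- function(pool, meta, labels, selection, seed = 1) {
  if (!identical(selection$kind, meta_kind(meta))) {
    stop("selection was computed on kind ", selection$kind,
         " but meta-features are ", meta_kind(meta), call. = FALSE)
  }
  x <- feature_matrix(meta)
  missing <- setdiff(selection$chosen_columns, colnames(x))
  if (length(missing)) stop("meta-features lack selected column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  clf <- make_classifier("RF", selection$meta_params, seed)
  clf <- fit_classifier(clf, x[, selection$chosen_columns, drop = FALSE],
                        as.numeric(labels))
  structure(list(pool = pool, selection = selection, meta = clf,
                 threshold = 0.5),
            class = "scorpion_model")
}

#' @export
print.scorpion_model <- function(x, ...) {
  cat("<scorpion_model> ", x$selection$kind, " meta-features, top-",
      x$selection$chosen_k, " of ", length(x$selection$ranking),
      "; pool of ", length(x$pool$members), " baselines\n", sep = "")
  invisible(x)
}

# Build the meta-feature tibble of the model's kind from a PF tibble.
meta_of_kind <- function(pf, kind) {
  switch(kind,
         PF = pf,
         CF = binarize_cf(pf),
         PCF = concat_pcf(pf, binarize_cf(pf)),
         stop("unknown meta-feature kind: ", kind, call. = FALSE))
}

#' Score protein records with a stacked model
#'
#' End-to-end prediction: encode the sequences with the pool's descriptors,
#' collect the 130 baseline probabilities, restrict to the selected
#' meta-features and apply the meta random forest. The predicted label is 1
#' when the meta probability is strictly greater than 0.5.
#'
#' @param model A `scorpion_model`.
#' @param records Tibble with `id` and `sequence` (see [read_fasta()]).
#' @param profiles Named list of `pssm_profile`, required when the pool uses
#'   PSSM descriptors.
#' @param ... Encoder options forwarded to [encode_features()].
#' @return Tibble with `id`, `probability`, `label`.
#' @export
predict_stacked <- function(model, records, profiles = NULL, ...) {
  feats <- encode_features(records, descriptors = model$pool$descriptors,
                           profiles = profiles, ...)
  pf <- pf_for_new_data(model$pool, feats)
  meta <- meta_of_kind(pf, model$selection$kind)
  x <- feature_matrix(meta)
  prob <- predict_prob(model$meta,
                       x[, model$selection$chosen_columns, drop = FALSE])
  tibble::tibble(id = records$id, probability = prob,
                 label = as.integer(prob > model$threshold))
}

#' Cross-validated metrics of the stacked model
#'
#' Pooled out-of-fold metrics of the meta random forest on the selected
#' columns of the (out-of-fold) training meta-features — the stacked
#' counterpart of each baseline's `cv_metrics`.
#'
#' @inheritParams fit_stacked
#' @param folds,seed Cross-validation controls.
#' @return One-row metrics tibble.
#' @export
stacked_cv_metrics <- function(meta, labels, selection, folds = 10, seed = 1) {
  x <- feature_matrix(meta)[, selection$chosen_columns, drop = FALSE]
  factory <- function(xt, yt) {
    clf <- fit_classifier(make_classifier("RF", selection$meta_params, seed), xt, yt)
    function(xnew) predict_prob(clf, xnew)
  }
  crossvalidate(factory, x, as.numeric(labels), folds, seed)$metrics
}

#' Save / load fitted objects
#'
#' Plain RDS serialization; round trips preserve member order and
#' predictions (including the gradient-boosting members).
#'
#' @param object A `baseline_pool` or `scorpion_model`.
#' @param path File path.
#' @return `path` (save) / the restored object (load).
#' @export
save_model <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
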