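# The ten baseline classifier families and the (descriptor x algorithm)
# baseline pool. Every family is wrapped behind a uniform fit /
# probability-of-positive interface so the stacking layer can treat members
# interchangeably. Families without native probabilities are adapted: SVM via
# libsvm's built-in Platt-style calibration, PLS as a regression on {0, 1}
# targets clipped to [0, 1].

#' Names of the 10 baseline classifier families
#' @export
ALGORITHM_NAMES <- c("DT", "ET", "KNN", "LR", "MLP", "NB", "PLS", "RF",
                     "SVM", "XGB")

# Families whose hyperparameters are tuned by cross-validated MCC; the rest
# run with their documented defaults.
TUNED_ALGORITHMS <- c("ET", "LR", "MLP", "RF", "SVM", "XGB")

mtry_from_rule <- function(rule, d) {
  switch(rule,
         sqrt = max(1L, floor(sqrt(d))),
         log2 = max(1L, floor(log2(d))),
         stop("unknown mtry rule: ", rule, call. = FALSE))
}

# Generic column renaming so formula-based learners never see exotic names.
vcolnames <- function(x) {
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

family_fit <- function(algorithm, x, y, params, seed) {
  yf <- factor(y, levels = c(0, 1))
  withr::with_seed(seed, switch(algorithm,
    DT = {
      df <- as.data.frame(vcolnames(x))
      df$.y <- yf
      list(fit = rpart::rpart(.y ~ ., data = df, method = "class"))
    },
    ET = list(fit = ranger::ranger(
      x = x, y = yf, probability = TRUE,
      num.trees = params$num.trees %||% 200,
      mtry = mtry_from_rule(params$mtry_rule %||% "sqrt", ncol(x)),
      splitrule = "extratrees", num.random.splits = 1,
      replace = FALSE, sample.fraction = 1,
      seed = seed, num.threads = 1)),
    KNN = list(train = x, y = yf, k = params$k %||% 5, seed = seed),
    LR = list(fit = glmnet::glmnet(
      x, yf, family = "binomial", alpha = 0,
      lambda = 1 / (params$C %||% 1)), lambda = 1 / (params$C %||% 1)),
    MLP = {
      mw <- (ncol(x) + 1) * (params$size %||% 32) + (params$size %||% 32) + 1
      list(fit = nnet::nnet(
        x, as.numeric(y), size = params$size %||% 32,
        decay = params$decay %||% 1e-4, maxit = params$maxit %||% 100,
        entropy = TRUE, trace = FALSE, MaxNWts = mw + 1))
    },
    NB = list(fit = e1071::naiveBayes(x, yf)),
    PLS = {
      keep <- which(apply(x, 2, stats::sd) > 0)
      ncomp <- min(params$ncomp %||% 5, length(keep), nrow(x) - 1)
      list(fit = mixOmics::pls(x[, keep, drop = FALSE], as.numeric(y),
                               ncomp = ncomp, mode = "regression"),
           keep = keep, ncomp = ncomp)
    },
    RF = list(fit = ranger::ranger(
      x = x, y = yf, probability = TRUE,
      num.trees = params$num.trees %||% 200,
      mtry = mtry_from_rule(params$mtry_rule %||% "sqrt", ncol(x)),
      seed = seed, num.threads = 1)),
    SVM = list(fit = suppressWarnings(e1071::svm(
      x, yf, kernel = "radial", cost = params$cost %||% 1,
      gamma = if (is.null(params$gamma) || is.na(params$gamma)) 1 / ncol(x)
              else params$gamma,
      probability = TRUE))),  # warns on constant columns; harmless here
    XGB = list(fit = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 3,
                    eta = params$eta %||% 0.3, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = params$nrounds %||% 50, verbose = 0)),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  ))
}

family_predict <- function(algorithm, fitted, x, seed = 1) {
  p <- switch(algorithm,
    DT = stats::predict(fitted$fit, as.data.frame(vcolnames(x)),
                        type = "prob")[, "1"],
    ET = stats::predict(fitted$fit, data = x,
                        num.threads = 1)$predictions[, "1"],
    KNN = withr::with_seed(seed, {
      pred <- class::knn(fitted$train, x, fitted$y, k = fitted$k, prob = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "1", pr, 1 - pr)
    }),
    LR = as.numeric(stats::predict(fitted$fit, x, s = fitted$lambda,
                                   type = "response")),
    MLP = as.numeric(stats::predict(fitted$fit, x)),
    NB = stats::predict(fitted$fit, x, type = "raw")[, "1"],
    PLS = {
      pr <- stats::predict(fitted$fit, x[, fitted$keep, drop = FALSE])
      pmin(1, pmax(0, as.numeric(pr$predict[, 1, fitted$ncomp])))
    },
    RF = stats::predict(fitted$fit, data = x,
                        num.threads = 1)$predictions[, "1"],
    SVM = {
      pred <- stats::predict(fitted$fit, x, probability = TRUE)
      attr(pred, "probabilities")[, "1"]
    },
    XGB = stats::predict(fitted$fit, xgboost::xgb.DMatrix(x, nthread = 1)),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
  unname(pmin(1, pmax(0, as.numeric(p))))
}

#' Construct a probability classifier of a given family
#'
#' Returns an unfitted classifier object supporting [fit_classifier()] and
#' [predict_prob()]. Families: decision tree (`DT`), extremely randomized
#' trees (`ET`), k-nearest neighbours (`KNN`), ridge-penalised logistic
#' regression (`LR`), multi-layer perceptron (`MLP`), Gaussian naive Bayes
#' (`NB`), partial least squares regression on 0/1 targets (`PLS`), random
#' forest (`RF`), RBF support vector machine with Platt-calibrated
#' probabilities (`SVM`) and gradient-boosted trees (`XGB`).
#'
#' @param algorithm One of `ALGORITHM_NAMES`.
#' @param params Named list of family hyperparameters (see grids in
#'   [default_grids()]); missing entries fall back to family defaults.
#' @param seed Integer seed used for every stochastic step of fitting and
#'   prediction.
#' @return An object of class `pvp_classifier`.
#' @export
make_classifier <- function(algorithm, params = list(), seed = 1) {
  if (!algorithm %in% ALGORITHM_NAMES) {
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  }
  structure(list(algorithm = algorithm, params = params, seed = seed,
                 fitted = NULL),
            class = "pvp_classifier")
}

#' Fit a classifier
#' @param clf A `pvp_classifier` from [make_classifier()].
#' @param x Numeric feature matrix (or feature tibble with id column).
#' @param y 0/1 labels aligned to rows.
#' @return The fitted classifier.
#' @export
fit_classifier <- function(clf, x, y) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  clf$fitted <- family_fit(clf$algorithm, x, as.numeric(y), clf$params, clf$seed)
  clf
}

#' Probability of the positive class
#' @param clf A fitted `pvp_classifier`.
#' @param x Feature matrix / tibble to score.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(clf, x) {
  if (is.null(clf$fitted)) stop("classifier is not fitted", call. = FALSE)
  if (is.data.frame(x)) x <- feature_matrix(x)
  family_predict(clf$algorithm, clf$fitted, x, clf$seed)
}

#' Default hyperparameter search grids
#'
#' Tuned families (`ET`, `LR`, `MLP`, `RF`, `SVM`, `XGB`) get a grid searched
#' by cross-validated MCC; the others (`DT`, `KNN`, `NB`, `PLS`) carry their
#' single default configuration. Enumeration order (first parameter varying
#' fastest, as produced by `expand.grid`) is the documented tie-break order.
#' `reduced = TRUE` collapses every grid to one sensible point for fast runs
#' on small data.
#'
#' @param reduced Use single-point grids.
#' @return Named list: algorithm -> list of parameter lists.
#' @export
default_grids <- function(reduced = FALSE) {
  as_points <- function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  if (reduced) {
    return(list(
      DT = list(list()),
      ET = list(list(num.trees = 200, mtry_rule = "sqrt")),
      KNN = list(list(k = 5)),
      LR = list(list(C = 1)),
      MLP = list(list(size = 4, decay = 0.01, maxit = 50)),
      NB = list(list()),
      PLS = list(list(ncomp = 5)),
      RF = list(list(num.trees = 200, mtry_rule = "sqrt")),
      SVM = list(list(cost = 1, gamma = NA)),
      XGB = list(list(max_depth = 3, eta = 0.3, nrounds = 50))
    ))
  }
  list(
    DT = list(list()),
    ET = as_points(expand.grid(num.trees = c(100, 200, 500),
                               mtry_rule = c("sqrt", "log2"),
                               stringsAsFactors = FALSE)),
    KNN = list(list(k = 5)),
    LR = as_points(expand.grid(C = c(0.01, 0.1, 1, 10, 100))),
    MLP = as_points(expand.grid(size = c(32, 64, 128),
                                decay = c(1e-4, 1e-3))),
    NB = list(list()),
    PLS = list(list(ncomp = 5)),
    RF = as_points(expand.grid(num.trees = c(100, 200, 500),
                               mtry_rule = c("sqrt", "log2"),
                               stringsAsFactors = FALSE)),
    SVM = as_points(expand.grid(cost = 2^seq(-5, 5, 2),
                                gamma = 2^seq(-15, 3, 2))),
    XGB = as_points(expand.grid(max_depth = c(3, 5, 7),
                                eta = c(0.05, 0.1, 0.3),
                                nrounds = c(100, 300)))
  )
}

#' Tune and fit one baseline model
#'
#' Evaluates every grid point by pooled out-of-fold MCC under stratified
#' cross-validation, picks the maximiser (ties: first point in grid order),
#' records the cross-validated metrics at the chosen point and refits it on
#' all data.
#'
#' @param features Feature tibble (or matrix) for one descriptor.
#' @param labels 0/1 labels.
#' @param algorithm Classifier family name.
#' @param descriptor Descriptor name (metadata only).
#' @param grid List of parameter lists; `NULL` uses [default_grids()].
#' @param folds,seed Cross-validation controls.
#' @return A `fitted_baseline`: list with `spec`, `chosen_params`,
#'   `cv_metrics` and the fitted `model`.
#' @export
tune_baseline <- function(features, labels, algorithm, descriptor = NA_character_,
                          grid = NULL, folds = 10, seed = 1) {
  x <- if (is.data.frame(features)) feature_matrix(features) else features
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present",
                                       call. = FALSE)
  if (nrow(x) < folds) {
    stop("n < folds; use fewer folds", call. = FALSE)
  }
  grid <- grid %||% default_grids()[[algorithm]]
  fold <- stratified_folds(labels, folds, seed)
  evals <- lapply(grid, function(params) {
    scores <- numeric(length(labels))
    for (f in seq_len(folds)) {
      tr <- fold != f
      clf <- make_classifier(algorithm, params, seed = seed + f)
      clf <- fit_classifier(clf, x[tr, , drop = FALSE], labels[tr])
      scores[!tr] <- predict_prob(clf, x[!tr, , drop = FALSE])
    }
    list(params = params, scores = scores,
         metrics = classification_metrics(labels, scores))
  })
  mccs <- vapply(evals, function(e) e$metrics$mcc, 0)
  best <- which.max(mccs)  # first max = first grid point on ties
  chosen <- evals[[best]]
  model <- fit_classifier(make_classifier(algorithm, chosen$params, seed), x,
                          labels)
  structure(list(
    spec = list(algorithm = algorithm, descriptor = descriptor, seed = seed),
    chosen_params = chosen$params,
    cv_metrics = chosen$metrics,
    cv_scores = chosen$scores,
    model = model
  ), class = "fitted_baseline")
}

#' @export
print.fitted_baseline <- function(x, ...) {
  cat("<fitted_baseline> ", x$spec$algorithm, "-", x$spec$descriptor,
      "  (cv MCC ", round(x$cv_metrics$mcc, 3), ")\n", sep = "")
  invisible(x)
}

#' Train the full baseline pool
#'
#' One tuned baseline per (descriptor, algorithm) pair, in descriptor-major,
#' algorithm-minor order (the serialised member order). With the 13
#' descriptors and 10 families this yields the 130-member pool.
#'
#' @param features_by_descriptor Named list of feature tibbles from
#'   [encode_features()], all row-aligned to the same records.
#' @param labels 0/1 labels aligned to rows.
#' @param algorithms Families to include (default all 10).
#' @param grids Named list of grids per family; `NULL` uses [default_grids()].
#' @param folds,seed Cross-validation controls; member seeds are derived
#'   from `seed`.
#' @return A `baseline_pool` object.
#' @export
train_pool <- function(features_by_descriptor, labels,
                       algorithms = ALGORITHM_NAMES, grids = NULL,
                       folds = 10, seed = 1) {
  ids <- lapply(features_by_descriptor, function(f) f$id)
  if (length(unique(ids)) != 1) {
    stop("descriptor matrices are not aligned to the same records",
         call. = FALSE)
  }
  if (length(ids[[1]]) != length(labels)) {
    stop("features/labels misaligned", call. = FALSE)
  }
  grids <- grids %||% default_grids()
  members <- list()
  i <- 0L
  for (d in names(features_by_descriptor)) {
    for (a in algorithms) {
      i <- i + 1L
      members[[paste0(a, "-", d)]] <- tune_baseline(
        features_by_descriptor[[d]], labels, algorithm = a, descriptor = d,
        grid = grids[[a]], folds = folds, seed = (seed + 97L * i) %% 2147483647L
      )
    }
  }
  structure(list(members = members,
                 descriptors = names(features_by_descriptor),
                 algorithms = algorithms, folds = folds, seed = seed),
            class = "baseline_pool")
}

#' @export
print.baseline_pool <- function(x, ...) {
  cat("<baseline_pool> ", length(x$members), " members (",
      length(x$descriptors), " descriptors x ", length(x$algorithms),
      " algorithms)\n", sep = "")
  invisible(x)
}

#' Probability predictions from one pool member
#' @param member A `fitted_baseline`.
#' @param features Feature tibble/matrix of the member's descriptor.
#' @return Probabilities of the positive class.
#' @export
predict_baseline <- function(member, features) {
  predict_prob(member$model, features)
}
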