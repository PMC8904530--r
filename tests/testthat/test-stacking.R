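# A slightly larger fixture reused across the stacking tests.
stack_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- tiny_pool_fixture(seed = 3)
      fx$pf <- generate_pf(fx$pool, fx$features, fx$records$label,
                           folds = 3, seed = 3)
      cache <<- fx
    }
    cache
  }
})

test_that("PF has one probability column per member, rows aligned", {
  fx <- stack_fixture()
  expect_equal(dim(fx$pf), c(30L, 7L))  # id + 6 members
  expect_equal(fx$pf$id, fx$records$id)
  vals <- as.matrix(fx$pf[-1])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(attr(fx$pf, "kind"), "PF")
  expect_length(attr(fx$pf, "fold"), 30)
  # separable data: positives score clearly above negatives
  sep <- colMeans(vals[fx$records$label == 1, , drop = FALSE]) -
    colMeans(vals[fx$records$label == 0, , drop = FALSE])
  expect_gt(max(sep), 0.5)
})

test_that("out-of-fold PF never comes from a model that saw the sample", {
  # A 1-NN member memorises its training set: in-sample PF reproduces the
  # labels exactly, out-of-fold PF cannot (labels are pure noise here).
  rec <- separable_records(15, delta = 0, seed = 20)
  feats <- encode_features(rec, descriptors = "AAC")
  pool <- train_pool(feats, rec$label, algorithms = "KNN",
                     grids = list(KNN = list(list(k = 1))), folds = 3, seed = 6)
  ins <- generate_pf(pool, feats, rec$label, folds = 3, seed = 6,
                     mode = "in-sample")
  expect_equal(as.numeric(ins[[2]]), as.numeric(rec$label))
  oof <- generate_pf(pool, feats, rec$label, folds = 3, seed = 6)
  expect_false(all(as.numeric(oof[[2]]) == as.numeric(rec$label)))
})

test_that("PF for new data is deterministic and member-aligned", {
  fx <- stack_fixture()
  newrec <- separable_records(4, seed = 55)
  newfeats <- encode_features(newrec, descriptors = c("AAC", "CTDC"))
  pf1 <- pf_for_new_data(fx$pool, newfeats)
  pf2 <- pf_for_new_data(fx$pool, newfeats)
  expect_identical(pf1, pf2)
  expect_equal(names(pf1)[-1], names(fx$pool$members))
  expect_true(all(as.matrix(pf1[-1]) >= 0 & as.matrix(pf1[-1]) <= 1))
  expect_error(pf_for_new_data(fx$pool, newfeats["AAC"]), "missing descriptor")
})

test_that("class features binarize strictly above one half", {
  pf <- pvpstack:::new_meta_matrix(
    matrix(c(0.7, 0.5, 0.3, 0.500001), 2, 2,
           dimnames = list(NULL, c("m1", "m2"))),
    c("a", "b"), "PF")
  cf <- binarize_cf(pf)
  expect_equal(unname(as.matrix(cf[-1])), matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(attr(cf, "kind"), "CF")
})

test_that("PCF concatenates PF then CF with disambiguated names", {
  fx <- stack_fixture()
  cf <- binarize_cf(fx$pf)
  pcf <- concat_pcf(fx$pf, cf)
  expect_equal(ncol(pcf) - 1L, 2L * (ncol(fx$pf) - 1L))
  expect_equal(attr(pcf, "kind"), "PCF")
  nm <- names(pcf)[-1]
  expect_true(all(endsWith(nm[1:6], ".PF")))
  expect_true(all(endsWith(nm[7:12], ".CF")))
  # PF block of any row is the PF row itself
  expect_equal(unname(as.matrix(pcf[3, 2:7])),
               unname(as.matrix(fx$pf[3, -1])))
  expect_error(concat_pcf(fx$pf, binarize_cf(fx$pf[1:10, ])), "not aligned")
})

test_that("importance ranking is a permutation that finds a perfect feature", {
  withr::with_seed(17, {
    n <- 100
    y <- rep(c(0, 1), each = n / 2)
    m <- matrix(runif(n * 12), n, 12)
    m[, 7] <- y  # label-identical column
    colnames(m) <- paste0("m", 1:12)
  })
  meta <- pvpstack:::new_meta_matrix(m, as.character(1:100), "PF")
  rk <- rank_features(meta, y, seed = 4)
  expect_setequal(rk, 1:12)
  expect_equal(rk[1], 7)
  expect_identical(rk, rank_features(meta, y, seed = 4))
  expect_error(rank_features(meta, rep(1, 100)), "both classes")
})

test_that("subset sweep stays inside the grid and drops oversized sizes", {
  fx <- stack_fixture()
  rk <- rank_features(fx$pf, fx$records$label, seed = 3)
  expect_warning(
    sel <- sweep_subsets(fx$pf, fx$records$label, rk, k_grid = c(2, 4, 50),
                         folds = 3, seed = 3, rf_grid = meta_rf_grid(TRUE)),
    "dropping")
  expect_true(sel$chosen_k %in% c(2, 4))
  expect_equal(sel$k_grid, c(2, 4))
  expect_equal(sel$chosen_columns,
               names(fx$pf)[-1][rk[seq_len(sel$chosen_k)]])
  expect_equal(nrow(sel$per_k), 2)
  expect_error(sweep_subsets(fx$pf, fx$records$label, rk, k_grid = numeric(0)),
               "empty")
  expect_error(suppressWarnings(
    sweep_subsets(fx$pf, fx$records$label, rk, k_grid = 1000, folds = 3)),
    "no usable")
})

test_that("default sweep grid has the 20 sizes top-5..top-100 step 5", {
  expect_equal(eval(formals(sweep_subsets)$k_grid), seq(5, 100, 5))
  expect_length(eval(formals(sweep_subsets)$k_grid), 20)
})

test_that("the stacked model fits on the chosen columns and round trips", {
  fx <- stack_fixture()
  rk <- rank_features(fx$pf, fx$records$label, seed = 3)
  sel <- suppressWarnings(sweep_subsets(
    fx$pf, fx$records$label, rk, k_grid = c(2, 4), folds = 3, seed = 3,
    rf_grid = meta_rf_grid(TRUE)))
  model <- fit_stacked(fx$pool, fx$pf, fx$records$label, sel, seed = 3)
  expect_s3_class(model, "scorpion_model")
  expect_equal(length(model$selection$chosen_columns), sel$chosen_k)

  pred <- predict_stacked(model, fx$records)
  expect_equal(nrow(pred), nrow(fx$records))
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_equal(pred$label, as.integer(pred$probability > 0.5))
  # strongly separable training positives score above one half
  expect_gt(mean(pred$probability[fx$records$label == 1] > 0.5), 0.9)
  expect_identical(pred, predict_stacked(model, fx$records))

  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  expect_identical(predict_stacked(load_model(f), fx$records), pred)

  # selection kind must match the meta-features being fit
  cf <- binarize_cf(fx$pf)
  expect_error(fit_stacked(fx$pool, cf, fx$records$label, sel), "kind")
})

test_that("PCF restricted to PF columns reproduces PF predictions", {
  fx <- stack_fixture()
  pcf <- concat_pcf(fx$pf, binarize_cf(fx$pf))
  cols <- names(fx$pf)[-1][1:3]
  xpf <- as.matrix(fx$pf[cols])
  xpcf <- as.matrix(pcf[paste0(cols, ".PF")])
  a <- fit_classifier(make_classifier("RF", list(num.trees = 100), seed = 2),
                      xpf, fx$records$label)
  b <- fit_classifier(make_classifier("RF", list(num.trees = 100), seed = 2),
                      xpcf, fx$records$label)
  expect_equal(predict_prob(a, xpf), predict_prob(b, xpcf))
})

test_that("the stacked model carries strong signal through on easy data", {
  fx <- stack_fixture()
  rk <- rank_features(fx$pf, fx$records$label, seed = 3)
  sel <- suppressWarnings(sweep_subsets(
    fx$pf, fx$records$label, rk, k_grid = c(2, 4), folds = 3, seed = 3,
    rf_grid = meta_rf_grid(TRUE)))
  scv <- stacked_cv_metrics(fx$pf, fx$records$label, sel, folds = 3, seed = 3)
  expect_gt(scv$mcc, 0.5)
  expect_gt(scv$auc, 0.8)
})
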