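# End-to-end workflow on a deliberately small configuration:
# 2 descriptors x 3 algorithms, 3 folds, k in {2, 4}.
small_config <- function(seed = 7) {
  run_config(descriptors = c("AAC", "CTDC"),
             algorithms = c("KNN", "LR", "RF"),
             folds = 3, seed = seed, k_grid = c(2, 4),
             reduced_grids = TRUE)
}

test_that("run_config validates its fields", {
  expect_s3_class(run_config(), "run_config")
  expect_error(run_config(descriptors = "NOPE"))
  expect_error(run_config(kind = "QF"))
  expect_error(run_config(folds = 1))
  expect_error(run_config(k_grid = numeric(0)))
})

test_that("cmd_synth writes FASTA, labels and profiles", {
  d <- withr::local_tempdir()
  cmd_synth(d, n_pos = 3, n_neg = 3, length_range = c(15, 25), seed = 4)
  expect_true(file.exists(file.path(d, "sequences.fasta")))
  expect_true(file.exists(file.path(d, "labels.tsv")))
  expect_length(list.files(file.path(d, "pssm")), 6)
})

test_that("cmd_encode writes one CSV per descriptor with declared widths", {
  d <- withr::local_tempdir()
  cmd_synth(d, n_pos = 3, n_neg = 3, length_range = c(15, 25), seed = 4)
  out <- file.path(d, "features")
  suppressMessages(
    cmd_encode(file.path(d, "sequences.fasta"), out,
               descriptors = c("AAC", "DPC", "PSSM_AAC"),
               pssm_dir = file.path(d, "pssm")))
  expect_setequal(list.files(out), c("AAC.csv", "DPC.csv", "PSSM_AAC.csv"))
  aac <- read_feature_csv(file.path(out, "AAC.csv"))
  expect_equal(ncol(aac) - 1L, 20L)
  expect_equal(ncol(read_feature_csv(file.path(out, "DPC.csv"))) - 1L, 400L)
  expect_error(
    cmd_encode(file.path(d, "sequences.fasta"), out,
               descriptors = "PSSM_AAC"), "pssm-dir")
})

test_that("train -> predict -> evaluate runs end to end from files", {
  d <- withr::local_tempdir()
  cmd_synth(d, n_pos = 15, n_neg = 15, length_range = c(40, 80),
            with_pssm = FALSE, seed = 7)
  model_path <- file.path(d, "model.rds")
  model <- cmd_train(file.path(d, "sequences.fasta"),
                     file.path(d, "labels.tsv"),
                     model_path, config = small_config(7))
  expect_true(file.exists(model_path))
  expect_s3_class(model, "scorpion_model")
  expect_equal(nrow(model$report$baselines), 6)
  expect_true(model$selection$chosen_k %in% c(2, 4))

  pred <- cmd_predict(model_path, file.path(d, "sequences.fasta"))
  expect_equal(nrow(pred), 30)
  expect_named(pred, c("id", "probability", "predicted_label"))
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_equal(pred$predicted_label,
               as.integer(pred$probability > 0.5))

  json <- file.path(d, "metrics.json")
  metrics <- cmd_evaluate(model_path, file.path(d, "sequences.fasta"),
                          file.path(d, "labels.tsv"), out = json)
  expect_named(metrics, c("acc", "sn", "sp", "mcc", "auc", "n"))
  parsed <- jsonlite::read_json(json)
  expect_setequal(names(parsed), c("acc", "sn", "sp", "mcc", "auc", "n"))
  # rounded to three decimals in the report
  expect_equal(parsed$acc, round(metrics$acc, 3))
})

test_that("training reproduces the chosen subset with the same seed", {
  rec <- separable_records(15, seed = 9)
  m1 <- train_scorpion(rec, config = small_config(9))
  m2 <- train_scorpion(rec, config = small_config(9))
  expect_equal(m1$selection$chosen_k, m2$selection$chosen_k)
  expect_equal(m1$selection$chosen_columns, m2$selection$chosen_columns)
  p1 <- predict_stacked(m1, rec)
  p2 <- predict_stacked(m2, rec)
  expect_equal(p1$probability, p2$probability)
  # the attached report mirrors the fitted objects
  expect_equal(nrow(m1$report$per_k), 2)
  expect_s3_class(m1$report$stacked_cv, "tbl_df")
})

test_that("training on a configuration with PSSM descriptors needs profiles", {
  rec <- separable_records(12, seed = 10)
  cfg <- run_config(descriptors = c("AAC", "PSSM_AAC"), algorithms = "RF",
                    folds = 3, seed = 10, k_grid = 2, reduced_grids = TRUE)
  expect_error(train_scorpion(rec, config = cfg), "no profile")
  prof <- generate_synthetic_pssms(rec, seed = 10)
  model <- train_scorpion(rec, profiles = prof, config = cfg)
  pred <- predict_stacked(model, rec, profiles = prof)
  expect_equal(nrow(pred), nrow(rec))
  expect_error(predict_stacked(model, rec), "no profile")
})

test_that("the command-line script completes a synth + encode round", {
  skip_if(Sys.which("Rscript") == "", "no Rscript on PATH")
  cli <- system.file("cli", "scorpion.R", package = "pvpstack")
  d <- withr::local_tempdir()
  status <- system2("Rscript",
                    c(cli, "synth", "--out", d, "--n-pos", "3", "--n-neg", "3",
                      "--no-pssm", "--seed", "2"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  expect_true(file.exists(file.path(d, "sequences.fasta")))
  status <- system2("Rscript",
                    c(cli, "encode", "--fasta", file.path(d, "sequences.fasta"),
                      "--out", file.path(d, "feat"), "--descriptors", "AAC"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  expect_true(file.exists(file.path(d, "feat", "AAC.csv")))
  # unknown subcommand exits nonzero
  status <- system2("Rscript", c(cli, "frobnicate"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 2)
})
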