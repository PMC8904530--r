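# High-level workflow: train/predict/evaluate on records, plus the file-based
# command functions wrapped by the `scorpion` command-line script
# (inst/cli/scorpion.R): synth / encode / train / predict / evaluate.

#' Build and validate a run configuration
#'
#' @param descriptors Descriptors to encode (default all 13).
#' @param algorithms Baseline families (default all 10).
#' @param folds Cross-validation folds (default 10).
#' @param seed Global integer seed (default 1).
#' @param kind Meta-feature kind to stack on: `"PF"` (default), `"CF"` or
#'   `"PCF"`.
#' @param k_grid Subset-sweep sizes (default 5..100 step 5).
#' @param reduced_grids Use single-point hyperparameter grids (fast runs).
#' @return Validated `run_config` list.
#' @export
run_config <- function(descriptors = DESCRIPTOR_NAMES,
                       algorithms = ALGORITHM_NAMES,
                       folds = 10, seed = 1, kind = "PF",
                       k_grid = seq(5, 100, 5), reduced_grids = FALSE) {
  stopifnot(all(descriptors %in% DESCRIPTOR_NAMES),
            all(algorithms %in% ALGORITHM_NAMES),
            kind %in% c("PF", "CF", "PCF"),
            folds >= 2, length(k_grid) >= 1, all(k_grid >= 1))
  structure(list(descriptors = descriptors, algorithms = algorithms,
                 folds = folds, seed = as.integer(seed), kind = kind,
                 k_grid = k_grid, reduced_grids = reduced_grids),
            class = "run_config")
}

#' Train a stacked phage-virion-protein model end to end
#'
#' Encodes the records, trains the baseline pool, generates out-of-fold
#' meta-features of the configured kind, runs the two-step feature selection
#' and fits the random-forest meta-model.
#'
#' @param records Labeled record tibble (`id`, `sequence`, `label`).
#' @param profiles Named list of `pssm_profile` (needed iff PSSM descriptors
#'   are configured).
#' @param config A [run_config()].
#' @param rf_grid Meta random-forest grid (default [meta_rf_grid()] honouring
#'   `config$reduced_grids`).
#' @param ... Encoder options forwarded to [encode_features()].
#' @return A `scorpion_model` with an attached `$report` (per-baseline CV
#'   table, per-k MCC curve, stacked CV metrics).
#' @export
train_scorpion <- function(records, profiles = NULL, config = run_config(),
                           rf_grid = NULL, ...) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(records$label)) stop("records need a `label` column", call. = FALSE)
  rf_grid <- rf_grid %||% meta_rf_grid(config$reduced_grids)
  feats <- encode_features(records, config$descriptors, profiles, ...)
  pool <- train_pool(feats, records$label,
                     algorithms = config$algorithms,
                     grids = default_grids(config$reduced_grids),
                     folds = config$folds, seed = config$seed)
  pf <- generate_pf(pool, feats, records$label,
                    folds = config$folds, seed = config$seed)
  meta <- meta_of_kind(pf, config$kind)
  ranking <- rank_features(meta, records$label, seed = config$seed)
  selection <- sweep_subsets(meta, records$label, ranking,
                             k_grid = config$k_grid, folds = config$folds,
                             seed = config$seed, rf_grid = rf_grid)
  model <- fit_stacked(pool, meta, records$label, selection, seed = config$seed)
  model$report <- list(
    baselines = generics::tidy(pool),
    per_k = selection$per_k[c("k", "acc", "sn", "sp", "mcc", "auc")],
    stacked_cv = stacked_cv_metrics(meta, records$label, selection,
                                    folds = config$folds, seed = config$seed),
    config = config
  )
  model
}

#' Evaluate a stacked model on labeled records
#'
#' @param model A `scorpion_model`.
#' @param records Labeled record tibble.
#' @param profiles PSSM profiles if the pool needs them.
#' @param ... Encoder options.
#' @return One-row metrics tibble (`acc`, `sn`, `sp`, `mcc`, `auc`, `n`).
#' @export
evaluate_scorpion <- function(model, records, profiles = NULL, ...) {
  if (is.null(records$label)) stop("records need a `label` column", call. = FALSE)
  pred <- predict_stacked(model, records, profiles, ...)
  classification_metrics(records$label, pred$probability, model$threshold)
}

# ---- file-based command functions (the CLI surface) ----

#' Generate a synthetic dataset on disk
#'
#' @param out_dir Output directory.
#' @param n_pos,n_neg,delta,length_range,bias_residues,bias_mode,seed See
#'   [synthetic_config()].
#' @param with_pssm Also write synthetic PSSM profiles.
#' @return The output directory, invisibly.
#' @export
cmd_synth <- function(out_dir, n_pos = 250, n_neg = 250, delta = 0.15,
                      length_range = c(50, 500),
                      bias_residues = c("C", "H", "K"),
                      bias_mode = "composition", with_pssm = TRUE, seed = 1) {
  cfg <- synthetic_config(n_pos, n_neg, length_range, bias_residues, delta,
                          bias_mode, seed)
  records <- generate_labeled_sequences(cfg)
  profiles <- if (with_pssm) generate_synthetic_pssms(records, seed = seed)
  write_synthetic_dataset(records, out_dir, profiles)
}

#' Encode a FASTA file into per-descriptor feature CSVs
#'
#' @param fasta Input FASTA path.
#' @param out_dir Output directory for `<descriptor>.csv` files.
#' @param descriptors Descriptors to encode.
#' @param pssm_dir Directory of `<id>.pssm` files (required for PSSM
#'   descriptors).
#' @param quiet Suppress the per-descriptor dimension log.
#' @param ... Encoder options.
#' @return Named character vector of written CSV paths, invisibly.
#' @export
cmd_encode <- function(fasta, out_dir, descriptors = DESCRIPTOR_NAMES,
                       pssm_dir = NULL, quiet = FALSE, ...) {
  records <- read_fasta(fasta)
  profiles <- NULL
  if (length(intersect(descriptors, PSSM_DESCRIPTORS))) {
    if (is.null(pssm_dir)) {
      stop("PSSM descriptor(s) requested but no --pssm-dir given", call. = FALSE)
    }
    profiles <- read_pssm_dir(records, pssm_dir)
  }
  feats <- encode_features(records, descriptors, profiles, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(feats), function(d) {
    p <- file.path(out_dir, paste0(d, ".csv"))
    write_feature_csv(feats[[d]], p)
    if (!quiet) message(d, ": ", ncol(feats[[d]]) - 1, " features")
    p
  }, "")
  invisible(paths)
}

#' Train a stacked model from files
#'
#' @param fasta Training FASTA.
#' @param labels Path to a two-column id/label TSV.
#' @param out_model Path for the serialized model (RDS).
#' @param config A [run_config()] or path to a YAML file with its fields.
#' @param pssm_dir PSSM directory if needed.
#' @return The fitted `scorpion_model`, invisibly.
#' @export
cmd_train <- function(fasta, labels, out_model, config = run_config(),
                      pssm_dir = NULL) {
  if (is.character(config)) {
    config <- do.call(run_config, yaml::read_yaml(config))
  }
  records <- read_fasta(fasta, label = read_label_table(labels))
  profiles <- NULL
  if (length(intersect(config$descriptors, PSSM_DESCRIPTORS))) {
    if (is.null(pssm_dir)) {
      stop("configured PSSM descriptors need --pssm-dir", call. = FALSE)
    }
    profiles <- read_pssm_dir(records, pssm_dir)
  }
  model <- train_scorpion(records, profiles, config)
  save_model(model, out_model)
  invisible(model)
}

#' Predict from files
#'
#' @param model_path Serialized `scorpion_model`.
#' @param fasta FASTA of sequences to score.
#' @param pssm_dir PSSM directory if the pool needs profiles.
#' @param out Optional TSV output path (`id`, `probability`,
#'   `predicted_label`).
#' @return Prediction tibble, invisibly if `out` is written.
#' @export
cmd_predict <- function(model_path, fasta, pssm_dir = NULL, out = NULL) {
  model <- load_model(model_path)
  records <- read_fasta(fasta)
  profiles <- NULL
  if (length(intersect(model$pool$descriptors, PSSM_DESCRIPTORS))) {
    if (is.null(pssm_dir)) stop("model needs PSSM profiles; give --pssm-dir",
                                call. = FALSE)
    profiles <- read_pssm_dir(records, pssm_dir)
  }
  pred <- predict_stacked(model, records, profiles)
  names(pred)[3] <- "predicted_label"
  if (!is.null(out)) {
    utils::write.table(pred, out, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(pred))
  }
  pred
}

#' Evaluate from files
#'
#' @inheritParams cmd_predict
#' @param labels Two-column id/label TSV for the scored FASTA.
#' @param out Optional JSON output path for the rounded metrics.
#' @return One-row metrics tibble (3-decimal rounding applied for the JSON).
#' @export
cmd_evaluate <- function(model_path, fasta, labels, pssm_dir = NULL,
                         out = NULL) {
  model <- load_model(model_path)
  records <- read_fasta(fasta, label = read_label_table(labels))
  profiles <- NULL
  if (length(intersect(model$pool$descriptors, PSSM_DESCRIPTORS))) {
    if (is.null(pssm_dir)) stop("model needs PSSM profiles; give --pssm-dir",
                                call. = FALSE)
    profiles <- read_pssm_dir(records, pssm_dir)
  }
  metrics <- evaluate_scorpion(model, records, profiles)
  if (!is.null(out)) {
    jsonlite::write_json(as.list(round_metrics(metrics)), out,
                         auto_unbox = TRUE, digits = NA)
  }
  metrics
}
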