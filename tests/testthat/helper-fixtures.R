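# Shared fixtures, all generated in code.

random_sequences <- function(n, min_len = 10, max_len = 30, seed = 42) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(pvpstack:::AA_ORDER, sample(min_len:max_len, 1),
                   replace = TRUE), collapse = "")
    }, "")
  })
}

# A small labeled record set with strong compositional separation.
separable_records <- function(n_per_class = 20, delta = 0.15, seed = 1,
                              len = c(40, 80)) {
  generate_labeled_sequences(synthetic_config(
    n_pos = n_per_class, n_neg = n_per_class, length_range = len,
    delta = delta, seed = seed))
}

# A tiny fitted pool for stacking tests: 2 descriptors x 3 algorithms.
tiny_pool_fixture <- function(seed = 3) {
  rec <- separable_records(15, seed = seed)
  feats <- encode_features(rec, descriptors = c("AAC", "CTDC"))
  pool <- train_pool(feats, rec$label, algorithms = c("KNN", "LR", "RF"),
                     grids = default_grids(TRUE), folds = 3, seed = seed)
  list(records = rec, features = feats, pool = pool)
}
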