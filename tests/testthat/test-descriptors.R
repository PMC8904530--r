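test_that("every descriptor has its declared dimension", {
  seq <- random_sequences(1, 25, 30, seed = 5)
  prof <- generate_synthetic_pssm(list(id = "x", sequence = seq), seed = 5)
  dims <- descriptor_dimensions()
  got <- c(AAC = length(encode_aac(seq)),
           AAI = length(encode_aai(seq)),
           APAAC = length(encode_apaac(seq)),
           CTDC = length(encode_ctdc(seq)),
           CTDD = length(encode_ctdd(seq)),
           CTDT = length(encode_ctdt(seq)),
           DDE = length(encode_dde(seq)),
           DPC = length(encode_dpc(seq)),
           EAAC = length(encode_eaac(seq)),
           PAAC = length(encode_paac(seq)),
           PSSM_AAC = length(encode_pssm_aac(prof)),
           PSSM_DP = length(encode_pssm_dp(prof)),
           PSSM_COM = length(encode_pssm_com(prof)))
  expect_equal(got, dims[names(got)])
  # lambda scales the pseudo-composition dims
  expect_length(encode_paac(seq, lam = 3), 23)
  expect_length(encode_apaac(seq, lam = 3), 26)
})

test_that("composition encoders handle canonical small cases", {
  aac <- encode_aac("AAAA")
  expect_equal(aac[["A"]], 1)
  expect_equal(sum(aac), 1)
  expect_equal(unname(encode_aac("ACDE")[c("A", "C", "D", "E")]), rep(0.25, 4))

  dpc <- encode_dpc("AC")
  expect_equal(dpc[["AC"]], 1)
  expect_equal(sum(dpc), 1)
  dpc2 <- encode_dpc("ACA")
  expect_equal(unname(dpc2[c("AC", "CA")]), c(0.5, 0.5))
  expect_error(encode_dpc("A"), "length")
  expect_error(encode_aac(""), "length")
})

# Reconstruction helpers for the Dc-sharing check below.
tm_table <- function() {
  ci <- pvpstack:::CODON_COUNTS[AA] / 61
  as.numeric(t(outer(ci, ci)))
}
sqrt_tv_for <- function(seq) {
  tm <- tm_table()
  sqrt(tm * (1 - tm) / (nchar(seq) - 1))
}

test_that("DDE matches its closed form and shares Dc with DPC", {
  # "AA": Dc = 1, Tm = (4/61)^2, Tv = Tm(1-Tm)/(L-1), L = 2
  tm <- (4 / 61)^2
  expected <- (1 - tm) / sqrt(tm * (1 - tm) / 1)
  expect_equal(encode_dde("AA")[["AA"]], expected)
  # absent dipeptides have Dc = 0
  expect_equal(encode_dde("AA")[["CC"]],
               (0 - (2 / 61)^2) / sqrt((2 / 61)^2 * (1 - (2 / 61)^2)))
  seq <- random_sequences(1, 20, 25, seed = 8)
  expect_equal(unname(encode_dde(seq) * sqrt_tv_for(seq) + tm_table()),
               unname(encode_dpc(seq)))
})

test_that("CTD behaves on homopolymers and the stated rounding rule", {
  ctd <- encode_ctd("AAAAA")
  # every property: composition 1 for A's group, transitions all zero
  expect_true(all(ctd$CTDT == 0))
  comp <- matrix(ctd$CTDC, nrow = 3)
  expect_true(all(colSums(comp) == 1))
  expect_true(all(apply(comp, 2, max) == 1))

  # distribution of "AAAA": ceil(q*n)-th occurrence, positions 1,1,2,3,4
  ctd4 <- encode_ctd("AAAA")
  d <- matrix(ctd4$CTDD, nrow = 5)
  occupied <- d[, colSums(d) > 0]
  expect_true(all(apply(occupied, 2, function(col)
    isTRUE(all.equal(col, c(25, 25, 50, 75, 100))))))
  # empty groups give five zeros
  expect_true(all(d[, colSums(d) == 0] == 0))
})

test_that("CTD values respect their ranges on random sequences", {
  for (seq in random_sequences(5, 15, 30, seed = 2)) {
    ctd <- encode_ctd(seq)
    comp <- matrix(ctd$CTDC, nrow = 3)
    expect_equal(unname(colSums(comp)), rep(1, 13))
    expect_true(all(ctd$CTDT >= 0 & ctd$CTDT <= 1))
    expect_true(all(ctd$CTDD >= 0 & ctd$CTDD <= 100))
  }
})

test_that("pseudo-compositions normalise to 1 and vanish on homopolymers", {
  p <- encode_paac("AAAAA")
  expect_equal(p[["A"]], 1)
  expect_equal(p[["lambda1"]], 0)  # zero correlation between identical residues
  a <- encode_apaac("AAAAA")
  expect_equal(sum(a), 1)
  for (seq in random_sequences(5, 12, 30, seed = 6)) {
    expect_equal(sum(encode_paac(seq, lam = 2)), 1)
    expect_equal(sum(encode_apaac(seq, lam = 2)), 1)
  }
  expect_error(encode_paac("AC", lam = 2), "length")
  expect_error(encode_apaac("AC", lam = 2), "length")
})

test_that("EAAC averages window compositions", {
  e <- encode_eaac("AAAAAA", window = 5)
  expect_equal(e[["A"]], 1)
  expect_true(all(e >= 0 & e <= 1))
  expect_error(encode_eaac("ACD", window = 5), "length")
})

test_that("AAI normalises indices and averages per position", {
  idx <- default_aaindex_set()
  v <- encode_aai("AAAA")
  manual <- vapply(idx, function(h) {
    h <- h[AA]
    (h[["A"]] - min(h)) / (max(h) - min(h))
  }, numeric(1))
  expect_equal(v, manual)
  broken <- idx
  broken[[1]] <- broken[[1]][-1]
  expect_error(encode_aai("ACDE", index_set = broken), "missing residue")
})

test_that("PSSM descriptors squash into [0,1] with the expected fixed points", {
  zero <- pvpstack:::new_pssm_profile("z", "AC",
                                      matrix(0, 2, 20,
                                             dimnames = list(NULL, PSSM_COLS)))
  expect_true(all(encode_pssm_aac(zero) == 0.5))
  expect_true(all(encode_pssm_dp(zero) == 0.25))
  com <- encode_pssm_com(zero)
  # only residues A and C present: all other 18 row blocks are zero
  blocks <- matrix(com, nrow = 20, byrow = TRUE)
  expect_true(all(blocks[-c(1, 2), ] == 0))
  expect_true(all(blocks[c(1, 2), ] == 0.5))

  one_row <- pvpstack:::new_pssm_profile("o", "A",
                                         matrix(1, 1, 20,
                                                dimnames = list(NULL, PSSM_COLS)))
  expect_error(encode_pssm_dp(one_row), "at least 2")
})

test_that("all encoders agree with brute-force oracles on random sequences", {
  seqs <- random_sequences(20, 10, 30, seed = 123)
  for (i in seq_along(seqs)) {
    seq <- seqs[i]
    prof <- generate_synthetic_pssm(list(id = "r", sequence = seq),
                                    concentration = 4, seed = 200 + i)
    expect_equal(unname(encode_aac(seq)), oracle_aac(seq))
    expect_equal(unname(encode_dpc(seq)), oracle_dpc(seq))
    expect_equal(unname(encode_dde(seq)), unname(oracle_dde(seq)))
    ctd <- encode_ctd(seq); octd <- oracle_ctd(seq)
    expect_equal(unname(ctd$CTDC), octd$C)
    expect_equal(unname(ctd$CTDT), octd$T)
    expect_equal(unname(ctd$CTDD), octd$D)
    expect_equal(unname(encode_paac(seq)), unname(oracle_paac(seq)))
    expect_equal(unname(encode_apaac(seq)), unname(oracle_apaac(seq)))
    expect_equal(unname(encode_eaac(seq)), oracle_eaac(seq))
    expect_equal(unname(encode_aai(seq)), unname(oracle_aai(seq)))
    expect_equal(unname(encode_pssm_aac(prof)), oracle_pssm_aac(prof))
    expect_equal(unname(encode_pssm_com(prof)), oracle_pssm_com(prof))
    expect_equal(unname(encode_pssm_dp(prof)), oracle_pssm_dp(prof))
  }
})

feature_matrix_of <- function(tbl) as.matrix(tbl[-1])

test_that("encode_features aligns rows, tags matrices and checks profiles", {
  rec <- separable_records(5, seed = 4)
  prof <- generate_synthetic_pssms(rec, seed = 4)
  feats <- encode_features(rec, profiles = prof)
  expect_named(feats, DESCRIPTOR_NAMES)
  for (d in names(feats)) {
    expect_equal(feats[[d]]$id, rec$id)
    expect_equal(ncol(feats[[d]]) - 1L, descriptor_dimensions()[[d]])
    expect_equal(attr(feats[[d]], "descriptor"), d)
    expect_true(all(is.finite(feature_matrix_of(feats[[d]]))))
  }
  # PSSM descriptors demand profiles, others do not
  expect_error(encode_features(rec, descriptors = c("AAC", "PSSM_AAC")),
               rec$id[1])
  expect_silent(encode_features(rec, descriptors = c("AAC", "DPC")))
  expect_error(encode_features(rec, descriptors = "BOGUS"), "unknown")
})

test_that("feature CSV round trip preserves values and names", {
  rec <- separable_records(3, seed = 10)
  feats <- encode_features(rec, descriptors = "PAAC")
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(feats$PAAC, f)
  back <- read_feature_csv(f, descriptor = "PAAC")
  expect_equal(back$id, feats$PAAC$id)
  expect_equal(as.matrix(back[-1]), as.matrix(feats$PAAC[-1]))
})

test_that("encoders are deterministic", {
  seq <- random_sequences(1, 30, 30, seed = 77)
  expect_identical(encode_apaac(seq), encode_apaac(seq))
  expect_identical(encode_ctd(seq), encode_ctd(seq))
})
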