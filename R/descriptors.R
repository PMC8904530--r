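# Sequence- and profile-based feature encoders. Each encoder maps one
# validated sequence (or one PSSM profile) to a fixed-length named numeric
# vector; encode_features() assembles per-descriptor feature matrices.

#' Names of the 13 feature descriptors
#' @export
DESCRIPTOR_NAMES <- c("AAC", "AAI", "APAAC", "CTDC", "CTDD", "CTDT", "DDE",
                      "DPC", "EAAC", "PAAC", "PSSM_AAC", "PSSM_DP", "PSSM_COM")

#' Descriptors that consume a PSSM profile rather than the raw sequence
#' @export
PSSM_DESCRIPTORS <- c("PSSM_AAC", "PSSM_DP", "PSSM_COM")

aa_counts <- function(chars) {
  tab <- table(factor(chars, levels = AA_ORDER))
  as.numeric(tab)
}

check_seq <- function(seq, min_len = 1) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(chars) < min_len) {
    stop("sequence must have length >= ", min_len, call. = FALSE)
  }
  if (any(!chars %in% AA_ORDER)) {
    stop("sequence contains non-standard residues; run validate_sequence() first",
         call. = FALSE)
  }
  chars
}

dipeptide_names <- function() paste0(rep(AA_ORDER, each = 20), rep(AA_ORDER, 20))

#' Amino-acid composition (AAC, 20-D)
#'
#' Frequency of each of the 20 standard residues, alphabetical order.
#'
#' @param seq Validated amino-acid sequence.
#' @return Named numeric vector of length 20 summing to 1.
#' @examples encode_aac("ACDE")
#' @export
encode_aac <- function(seq) {
  chars <- check_seq(seq, 1)
  stats::setNames(aa_counts(chars) / length(chars), AA_ORDER)
}

#' Dipeptide composition (DPC, 400-D)
#'
#' Frequency of each ordered residue pair among the `L - 1` adjacent pairs.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400 summing to 1.
#' @export
encode_dpc <- function(seq) {
  chars <- check_seq(seq, 2)
  L <- length(chars)
  pairs <- paste0(chars[-L], chars[-1])
  tab <- table(factor(pairs, levels = dipeptide_names()))
  stats::setNames(as.numeric(tab) / (L - 1), dipeptide_names())
}

#' Dipeptide deviation from expected mean (DDE, 400-D)
#'
#' For each dipeptide, the observed composition `Dc` is compared with its
#' theoretical mean `Tm(i,j) = (Ci/61)(Cj/61)` under the synonymous-codon
#' usage of the standard genetic code (`Ci` sense-codon count of residue i)
#' and variance `Tv = Tm(1 - Tm)/(L - 1)`:
#' `DDE = (Dc - Tm) / sqrt(Tv)`.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400.
#' @export
encode_dde <- function(seq) {
  chars <- check_seq(seq, 2)
  L <- length(chars)
  dc <- encode_dpc(seq)
  ci <- CODON_COUNTS[AA_ORDER] / 61
  tm <- as.numeric(t(outer(ci, ci)))  # row-major: first residue major
  tv <- tm * (1 - tm) / (L - 1)
  stats::setNames((dc - tm) / sqrt(tv), dipeptide_names())
}

ctd_group_index <- function(chars, groups) {
  g <- integer(length(chars))
  for (k in 1:3) {
    g[chars %in% strsplit(groups[k], "")[[1]]] <- k
  }
  g
}

#' Composition / transition / distribution descriptors (CTD)
#'
#' Thirteen physicochemical properties each partition the residues into three
#' groups (see `CTD_GROUPS`). Composition (`CTDC`, 39-D) is the fraction of
#' residues per group. Transition (`CTDT`, 39-D) is, per property, the
#' fraction of adjacent pairs crossing each group-pair boundary (1-2, 1-3,
#' 2-3, either direction) among the `L - 1` pairs. Distribution (`CTDD`,
#' 195-D) locates, per group, the 1st, 25%, 50%, 75% and 100% occurrence
#' (the `ceiling(q * n_group)`-th occurrence) and reports its position as
#' `100 * position / L`; an absent group yields five zeros.
#'
#' @inheritParams encode_aac
#' @return List with components `CTDC` (39), `CTDT` (39) and `CTDD` (195),
#'   each a named numeric vector.
#' @export
encode_ctd <- function(seq) {
  chars <- check_seq(seq, 2)
  L <- length(chars)
  comp <- trans <- numeric(0)
  dist <- numeric(0)
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  qlab <- c("first", "25", "50", "75", "100")
  for (prop in names(CTD_GROUPS)) {
    g <- ctd_group_index(chars, CTD_GROUPS[[prop]])
    cn <- tabulate(g, 3)
    comp <- c(comp, stats::setNames(cn / L, paste0(prop, ".G", 1:3)))
    a <- g[-L]; b <- g[-1]
    tr <- c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
            sum((a == 1 & b == 3) | (a == 3 & b == 1)),
            sum((a == 2 & b == 3) | (a == 3 & b == 2))) / (L - 1)
    trans <- c(trans, stats::setNames(tr, paste0(prop, ".T", c("12", "13", "23"))))
    for (k in 1:3) {
      pos <- which(g == k)
      n <- length(pos)
      d <- if (n == 0) rep(0, 5) else {
        idx <- pmax(1, ceiling(qs * n))
        100 * pos[idx] / L
      }
      dist <- c(dist, stats::setNames(d, paste0(prop, ".G", k, ".", qlab)))
    }
  }
  list(CTDC = comp, CTDT = trans, CTDD = dist)
}

#' @rdname encode_ctd
#' @export
encode_ctdc <- function(seq) encode_ctd(seq)$CTDC

#' @rdname encode_ctd
#' @export
encode_ctdt <- function(seq) encode_ctd(seq)$CTDT

#' @rdname encode_ctd
#' @export
encode_ctdd <- function(seq) encode_ctd(seq)$CTDD

paac_theta <- function(chars, lam, props) {
  L <- length(chars)
  vapply(seq_len(lam), function(k) {
    i <- seq_len(L - k)
    mean(rowMeans(vapply(props, function(h) (h[chars[i + k]] - h[chars[i]])^2,
                         numeric(L - k))))
  }, numeric(1))
}

#' Pseudo amino-acid composition (PAAC, 20 + lambda dims)
#'
#' Classic pseudo amino-acid composition over three standardised residue
#' properties (hydrophobicity, hydrophilicity, side-chain mass). The first
#' 20 entries are residue frequencies and the last `lam` entries are the
#' weighted sequence-order correlation factors `theta_k` (mean squared
#' property difference at gap k); all entries are normalised by
#' `1 + w * sum(theta)` so the vector sums to 1.
#'
#' @inheritParams encode_aac
#' @param lam Maximum sequence-order gap (default 1, giving the 21-D vector).
#' @param w Weight of the sequence-order terms (default 0.05).
#' @return Named numeric vector of length `20 + lam` summing to 1.
#' @export
encode_paac <- function(seq, lam = 1, w = 0.05) {
  chars <- check_seq(seq, lam + 1)
  if (lam < 1) stop("`lam` must be a positive integer", call. = FALSE)
  props <- lapply(list(PAAC_HYDROPHOBICITY, PAAC_HYDROPHILICITY,
                       PAAC_SIDECHAIN_MASS), paac_normalise)
  theta <- paac_theta(chars, lam, props)
  f <- aa_counts(chars) / length(chars)
  denom <- 1 + w * sum(theta)
  stats::setNames(c(f, w * theta) / denom,
                  c(AA_ORDER, paste0("lambda", seq_len(lam))))
}

#' Amphiphilic pseudo amino-acid composition (APAAC, 20 + 2*lambda dims)
#'
#' As [encode_paac()] but the sequence-order terms are separate hydrophobicity
#' and hydrophilicity correlation factors:
#' `tau_{2k-1} = mean(H1_i * H1_{i+k})`, `tau_{2k} = mean(H2_i * H2_{i+k})`.
#'
#' @inheritParams encode_paac
#' @return Named numeric vector of length `20 + 2 * lam` summing to 1.
#' @export
encode_apaac <- function(seq, lam = 1, w = 0.05) {
  chars <- check_seq(seq, lam + 1)
  if (lam < 1) stop("`lam` must be a positive integer", call. = FALSE)
  h1 <- paac_normalise(PAAC_HYDROPHOBICITY)
  h2 <- paac_normalise(PAAC_HYDROPHILICITY)
  L <- length(chars)
  tau <- numeric(2 * lam)
  for (k in seq_len(lam)) {
    i <- seq_len(L - k)
    tau[2 * k - 1] <- mean(h1[chars[i]] * h1[chars[i + k]])
    tau[2 * k]     <- mean(h2[chars[i]] * h2[chars[i + k]])
  }
  f <- aa_counts(chars) / L
  denom <- 1 + w * sum(tau)
  nm <- c(AA_ORDER,
          paste0(rep(c("Hphob", "Hphil"), lam), ".tau", rep(seq_len(lam), each = 2)))
  stats::setNames(c(f, w * tau) / denom, nm)
}

#' Windowed (enhanced) amino-acid composition (EAAC, 20-D)
#'
#' Amino-acid composition inside every sliding window of size `window`,
#' averaged over the `L - window + 1` windows into a fixed 20-vector.
#'
#' @inheritParams encode_aac
#' @param window Sliding-window size (default 5).
#' @return Named numeric vector of length 20.
#' @export
encode_eaac <- function(seq, window = 5) {
  chars <- check_seq(seq, window)
  L <- length(chars)
  idx <- match(chars, AA_ORDER)
  onehot <- matrix(0, L, 20)
  onehot[cbind(seq_len(L), idx)] <- 1
  cs <- rbind(0, apply(onehot, 2, cumsum))
  wins <- (cs[(window + 1):(L + 1), , drop = FALSE] -
             cs[1:(L - window + 1), , drop = FALSE]) / window
  stats::setNames(colMeans(wins), AA_ORDER)
}

#' AAindex property descriptor (AAI, 11-D)
#'
#' Each of the 11 residue property scales is min-max normalised to `[0, 1]`
#' over the 20 residues, then averaged over sequence positions.
#'
#' @inheritParams encode_aac
#' @param index_set Named list of residue property tables; defaults to
#'   [default_aaindex_set()].
#' @return Named numeric vector, one entry per property scale.
#' @export
encode_aai <- function(seq, index_set = default_aaindex_set()) {
  chars <- check_seq(seq, 1)
  vapply(index_set, function(h) {
    if (!all(AA_ORDER %in% names(h))) {
      stop("AAindex table missing residue(s): ",
           paste(setdiff(AA_ORDER, names(h)), collapse = ", "), call. = FALSE)
    }
    h <- h[AA_ORDER]
    hn <- (h - min(h)) / (max(h) - min(h))
    mean(hn[chars])
  }, numeric(1))
}

squash_pssm <- function(scores, squash = c("sigmoid", "identity", "minmax")) {
  squash <- match.arg(squash)
  switch(squash,
    sigmoid = 1 / (1 + exp(-scores)),
    identity = scores,
    minmax = {
      rng <- range(scores)
      if (rng[1] == rng[2]) matrix(0.5, nrow(scores), ncol(scores),
                                   dimnames = dimnames(scores))
      else (scores - rng[1]) / (rng[2] - rng[1])
    })
}

#' Profile amino-acid composition (PSSM_AAC, 20-D)
#'
#' Column-wise mean of the squashed PSSM: each log-odds score is passed
#' through the logistic function (default) and averaged down each of the 20
#' profile columns.
#'
#' @param profile A `pssm_profile` from [read_pssm()].
#' @param squash Score transform: `"sigmoid"` (default), `"identity"` or
#'   `"minmax"`.
#' @return Named numeric vector of length 20 (PSI-BLAST column order).
#' @export
encode_pssm_aac <- function(profile, squash = "sigmoid") {
  stopifnot(inherits(profile, "pssm_profile"))
  s <- squash_pssm(profile$scores, squash)
  stats::setNames(colMeans(s), paste0("p", PSSM_COL_ORDER))
}

#' Profile composition by residue (PSSM_COM, 400-D)
#'
#' Squashed profile rows are grouped by the residue actually observed at each
#' position; row block r is the mean profile row over positions holding
#' residue r (zero block if the residue is absent). Blocks are ordered
#' alphabetically by residue and flattened row-major.
#'
#' @inheritParams encode_pssm_aac
#' @return Named numeric vector of length 400.
#' @export
encode_pssm_com <- function(profile, squash = "sigmoid") {
  stopifnot(inherits(profile, "pssm_profile"))
  s <- squash_pssm(profile$scores, squash)
  res <- strsplit(profile$residues, "")[[1]]
  out <- matrix(0, 20, 20, dimnames = list(AA_ORDER, PSSM_COL_ORDER))
  for (r in unique(res)) {
    if (r %in% AA_ORDER) {
      out[r, ] <- colMeans(s[res == r, , drop = FALSE])
    }
  }
  stats::setNames(as.numeric(t(out)),
                  paste0(rep(AA_ORDER, each = 20), ".p", rep(PSSM_COL_ORDER, 20)))
}

#' Profile dipeptide composition (PSSM_DP, 400-D)
#'
#' Dipeptide-style products of consecutive squashed profile rows:
#' `value[(j,k)] = mean_i s[i,j] * s[i+1,k]` over the `L - 1` consecutive
#' position pairs.
#'
#' @inheritParams encode_pssm_aac
#' @return Named numeric vector of length 400.
#' @export
encode_pssm_dp <- function(profile, squash = "sigmoid") {
  stopifnot(inherits(profile, "pssm_profile"))
  L <- nrow(profile$scores)
  if (L < 2) stop("PSSM must have at least 2 rows for PSSM_DP", call. = FALSE)
  s <- squash_pssm(profile$scores, squash)
  m <- crossprod(s[-L, , drop = FALSE], s[-1, , drop = FALSE]) / (L - 1)
  stats::setNames(as.numeric(t(m)),
                  paste0(rep(PSSM_COL_ORDER, each = 20), ".p",
                         rep(PSSM_COL_ORDER, 20)))
}

encoder_for <- function(descriptor, lam = 1, w = 0.05, window = 5,
                        index_set = default_aaindex_set(), squash = "sigmoid") {
  switch(descriptor,
    AAC = function(rec, prof) encode_aac(rec),
    AAI = function(rec, prof) encode_aai(rec, index_set),
    APAAC = function(rec, prof) encode_apaac(rec, lam, w),
    CTDC = function(rec, prof) encode_ctdc(rec),
    CTDD = function(rec, prof) encode_ctdd(rec),
    CTDT = function(rec, prof) encode_ctdt(rec),
    DDE = function(rec, prof) encode_dde(rec),
    DPC = function(rec, prof) encode_dpc(rec),
    EAAC = function(rec, prof) encode_eaac(rec, window),
    PAAC = function(rec, prof) encode_paac(rec, lam, w),
    PSSM_AAC = function(rec, prof) encode_pssm_aac(prof, squash),
    PSSM_COM = function(rec, prof) encode_pssm_com(prof, squash),
    PSSM_DP = function(rec, prof) encode_pssm_dp(prof, squash),
    stop("unknown descriptor: ", descriptor, call. = FALSE))
}

#' Encode a set of records with one or more feature descriptors
#'
#' Runs each requested encoder over every record and assembles one feature
#' matrix per descriptor, rows aligned to record order.
#'
#' @param records Tibble with `id` and `sequence` columns (see [read_fasta()]).
#' @param descriptors Character vector of descriptor names; default all 13.
#' @param profiles Named list of `pssm_profile` keyed by record id; required
#'   only when a PSSM descriptor is requested.
#' @param lam,w PAAC/APAAC parameters.
#' @param window EAAC window size.
#' @param index_set AAI property tables.
#' @param squash PSSM score transform.
#' @return Named list of tibbles; each has `id` as its first column followed
#'   by the descriptor's named feature columns, and carries the descriptor
#'   name in attribute `"descriptor"`.
#' @export
encode_features <- function(records, descriptors = DESCRIPTOR_NAMES,
                            profiles = NULL, lam = 1, w = 0.05, window = 5,
                            index_set = default_aaindex_set(),
                            squash = "sigmoid") {
  bad <- setdiff(descriptors, DESCRIPTOR_NAMES)
  if (length(bad)) stop("unknown descriptor(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  needs_pssm <- intersect(descriptors, PSSM_DESCRIPTORS)
  if (length(needs_pssm)) {
    missing <- setdiff(records$id, names(profiles))
    if (length(missing)) {
      stop("PSSM descriptor(s) requested but no profile for record(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  out <- lapply(descriptors, function(d) {
    enc <- encoder_for(d, lam, w, window, index_set, squash)
    vecs <- purrr::map2(records$sequence, records$id,
                        function(s, id) enc(s, profiles[[id]]))
    mat <- do.call(rbind, vecs)
    tbl <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
    tbl <- dplyr::bind_cols(tibble::tibble(id = records$id), tbl)
    attr(tbl, "descriptor") <- d
    tbl
  })
  stats::setNames(out, descriptors)
}

#' Declared dimensions of the 13 descriptors
#'
#' @param lam PAAC/APAAC gap parameter (affects their dimensions).
#' @return Named integer vector.
#' @export
descriptor_dimensions <- function(lam = 1) {
  c(AAC = 20L, AAI = 11L, APAAC = as.integer(20 + 2 * lam), CTDC = 39L,
    CTDD = 195L, CTDT = 39L, DDE = 400L, DPC = 400L, EAAC = 20L,
    PAAC = as.integer(20 + lam), PSSM_AAC = 20L, PSSM_DP = 400L,
    PSSM_COM = 400L)
}

#' Write / read a feature matrix as CSV
#'
#' CSV with a header row of column names; first column is the record id.
#'
#' @param features Feature tibble from [encode_features()].
#' @param path File path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @param descriptor Optional descriptor tag to attach on read.
#' @export
read_feature_csv <- function(path, descriptor = NULL) {
  tbl <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                           colClasses = c("character")))
  tbl[-1] <- lapply(tbl[-1], as.numeric)
  names(tbl)[1] <- "id"
  if (!is.null(descriptor)) attr(tbl, "descriptor") <- descriptor
  tbl
}

# Strip the id column of a feature tibble into a plain numeric matrix.
feature_matrix <- function(features) {
  m <- as.matrix(features[setdiff(names(features), "id")])
  rownames(m) <- features$id
  storage.mode(m) <- "double"
  m
}
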