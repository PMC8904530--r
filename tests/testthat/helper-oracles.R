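# Independent brute-force re-implementations of every encoder, written as
# plain loops. These act as oracles: they share only the published constants
# (alphabet, groupings, property tables) with the package, never its code
# paths.

AA <- pvpstack:::AA_ORDER
PSSM_COLS <- pvpstack:::PSSM_COL_ORDER

oracle_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(20)
  for (i in seq_along(AA)) {
    for (c in ch) if (c == AA[i]) out[i] <- out[i] + 1
  }
  out / length(ch)
}

oracle_dpc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(400)
  idx <- 0
  for (a in AA) for (b in AA) {
    idx <- idx + 1
    for (i in 1:(length(ch) - 1)) {
      if (ch[i] == a && ch[i + 1] == b) out[idx] <- out[idx] + 1
    }
  }
  out / (length(ch) - 1)
}

oracle_dde <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  cc <- pvpstack:::CODON_COUNTS
  dc <- oracle_dpc(seq)
  out <- numeric(400)
  idx <- 0
  for (a in AA) for (b in AA) {
    idx <- idx + 1
    tm <- (cc[[a]] / 61) * (cc[[b]] / 61)
    tv <- tm * (1 - tm) / (L - 1)
    out[idx] <- (dc[idx] - tm) / sqrt(tv)
  }
  out
}

oracle_ctd <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  groups <- pvpstack:::CTD_GROUPS
  comp <- c(); trans <- c(); dist <- c()
  for (prop in names(groups)) {
    gsets <- lapply(groups[[prop]], function(s) strsplit(s, "")[[1]])
    g <- vapply(ch, function(c) which(vapply(gsets, function(s) c %in% s, TRUE)),
                integer(1))
    for (k in 1:3) comp <- c(comp, sum(g == k) / L)
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    for (p in pairs) {
      n <- 0
      for (i in 1:(L - 1)) {
        if ((g[i] == p[1] && g[i + 1] == p[2]) ||
            (g[i] == p[2] && g[i + 1] == p[1])) n <- n + 1
      }
      trans <- c(trans, n / (L - 1))
    }
    for (k in 1:3) {
      pos <- which(g == k)
      if (length(pos) == 0) { dist <- c(dist, rep(0, 5)); next }
      for (q in c(0, 0.25, 0.5, 0.75, 1)) {
        i <- max(1, ceiling(q * length(pos)))
        dist <- c(dist, 100 * unname(pos[i]) / L)
      }
    }
  }
  list(C = comp, T = trans, D = dist)
}

oracle_norm_prop <- function(h) {
  h <- h[AA]
  m <- sum(h) / 20
  s <- sqrt(sum((h - m)^2) / 20)
  (h - m) / s
}

oracle_paac <- function(seq, lam = 1, w = 0.05) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  props <- list(oracle_norm_prop(pvpstack:::PAAC_HYDROPHOBICITY),
                oracle_norm_prop(pvpstack:::PAAC_HYDROPHILICITY),
                oracle_norm_prop(pvpstack:::PAAC_SIDECHAIN_MASS))
  theta <- numeric(lam)
  for (k in 1:lam) {
    tot <- 0
    for (i in 1:(L - k)) {
      s <- 0
      for (p in props) s <- s + (p[ch[i + k]] - p[ch[i]])^2
      tot <- tot + s / 3
    }
    theta[k] <- tot / (L - k)
  }
  f <- oracle_aac(seq)
  c(f, w * theta) / (1 + w * sum(theta))
}

oracle_apaac <- function(seq, lam = 1, w = 0.05) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  h1 <- oracle_norm_prop(pvpstack:::PAAC_HYDROPHOBICITY)
  h2 <- oracle_norm_prop(pvpstack:::PAAC_HYDROPHILICITY)
  tau <- numeric(2 * lam)
  for (k in 1:lam) {
    s1 <- 0; s2 <- 0
    for (i in 1:(L - k)) {
      s1 <- s1 + h1[ch[i]] * h1[ch[i + k]]
      s2 <- s2 + h2[ch[i]] * h2[ch[i + k]]
    }
    tau[2 * k - 1] <- s1 / (L - k)
    tau[2 * k] <- s2 / (L - k)
  }
  f <- oracle_aac(seq)
  c(f, w * tau) / (1 + w * sum(tau))
}

oracle_eaac <- function(seq, window = 5) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  acc <- numeric(20)
  nw <- L - window + 1
  for (s in 1:nw) {
    win <- ch[s:(s + window - 1)]
    for (i in seq_along(AA)) acc[i] <- acc[i] + sum(win == AA[i]) / window
  }
  acc / nw
}

oracle_aai <- function(seq, index_set = default_aaindex_set()) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(length(index_set))
  for (j in seq_along(index_set)) {
    h <- index_set[[j]][AA]
    hn <- (h - min(h)) / (max(h) - min(h))
    tot <- 0
    for (c in ch) tot <- tot + hn[[c]]
    out[j] <- tot / length(ch)
  }
  out
}

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

oracle_pssm_aac <- function(profile) {
  s <- profile$scores
  out <- numeric(20)
  for (j in 1:20) {
    for (i in 1:nrow(s)) out[j] <- out[j] + oracle_sigmoid(s[i, j])
    out[j] <- out[j] / nrow(s)
  }
  out
}

oracle_pssm_com <- function(profile) {
  s <- profile$scores
  res <- strsplit(profile$residues, "")[[1]]
  out <- numeric(400)
  idx <- 0
  for (r in AA) {
    rows <- which(res == r)
    for (j in 1:20) {
      idx <- idx + 1
      if (length(rows)) {
        tot <- 0
        for (i in rows) tot <- tot + oracle_sigmoid(s[i, j])
        out[idx] <- tot / length(rows)
      }
    }
  }
  out
}

oracle_pssm_dp <- function(profile) {
  s <- profile$scores
  L <- nrow(s)
  out <- numeric(400)
  idx <- 0
  for (j in 1:20) for (k in 1:20) {
    idx <- idx + 1
    tot <- 0
    for (i in 1:(L - 1)) {
      tot <- tot + oracle_sigmoid(s[i, j]) * oracle_sigmoid(s[i + 1, k])
    }
    out[idx] <- tot / (L - 1)
  }
  out
}

# Trapezoidal ROC-integration AUC, independent of the rank-based routine.
oracle_auc_trapezoid <- function(labels, scores) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    tpr[i] <- sum(scores >= thr[i] & labels == 1) / n1
    fpr[i] <- sum(scores >= thr[i] & labels == 0) / n0
  }
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}
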