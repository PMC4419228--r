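# Shared fixtures and independent oracles used across the suite.

# Tiny class dataset built directly from a samples x channels matrix.
make_dataset <- function(X, label = "A") {
  recs <- lapply(seq_len(ncol(X)), function(j) {
    signal_record(X[, j], channel_id = sprintf("%s_%02d", label, j),
                  class_label = label)
  })
  class_dataset(recs, class_label = label)
}

# Brute-force optimum-allocation shares: literal transcription of the
# allocation formula, one stratum at a time.
oracle_allocation_shares <- function(N, s2, m) {
  k <- length(N)
  w <- numeric(k)
  for (i in seq_len(k)) {
    tot <- 0
    for (j in seq_len(ncol(s2))) tot <- tot + s2[i, j]
    w[i] <- N[i] * sqrt(tot)
  }
  sapply(seq_len(k), function(i) w[i] / sum(w) * m)
}

# Moment oracle with Kahan-compensated summation: an independent,
# extended-precision route to mean, SD, skewness and excess kurtosis.
kahan_sum <- function(v) {
  s <- 0; c <- 0
  for (x in v) {
    y <- x - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

oracle_moments <- function(v) {
  n <- length(v)
  mu <- kahan_sum(v) / n
  m2 <- kahan_sum((v - mu)^2) / n
  m3 <- kahan_sum((v - mu)^3) / n
  m4 <- kahan_sum((v - mu)^4) / n
  c(mean = mu,
    sd = sqrt(kahan_sum((v - mu)^2) / (n - 1)),
    skew = m3 / m2^1.5,
    exkurt = m4 / m2^2 - 3)
}

# Pairwise-comparison ROC area: P(score_pos > score_neg) + half ties.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Write a small corpus directory of ASCII channel files; returns root.
write_tmp_corpus <- function(values_by_class, root = withr::local_tempdir(
                               .local_envir = parent.frame())) {
  for (cl in names(values_by_class)) {
    d <- file.path(root, cl)
    dir.create(d, recursive = TRUE)
    chans <- values_by_class[[cl]]
    for (j in seq_along(chans)) {
      writeLines(as.character(chans[[j]]),
                 file.path(d, sprintf("ch%02d.txt", j)))
    }
  }
  root
}

# Deterministic two-cluster training fixture for classifier tests.
two_cluster_fixture <- function(n_per = 10, gap = 10, seed = 42) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * 2, 0, 0.5), ncol = 2),
               matrix(rnorm(n_per * 2, gap, 0.5), ncol = 2))
    list(X = X, y = rep(c("A", "B"), each = n_per))
  })
}
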