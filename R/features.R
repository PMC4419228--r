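# The eleven per-channel statistics and feature-matrix assembly.
#
# Conventions (each deterministic so the pipeline is exactly repeatable):
# quartiles by linear interpolation at rank (n - 1) q; SD with the n - 1
# denominator; skewness and kurtosis as biased central-moment ratios, the
# kurtosis reported as EXCESS so a normal signal scores 0; mode as the
# midpoint of the fullest bin of an equal-width histogram with
# ceiling(sqrt(n)) bins.

#' Linear-interpolation quantile
#'
#' Order-statistic quantile at rank `h = (n - 1) q` with linear
#' interpolation between adjacent order statistics (the common "type 7"
#' convention).
#'
#' @param values Non-empty numeric vector, all finite.
#' @param q Probability in `[0, 1]`.
#' @return The interpolated quantile.
#' @export
quantile_linear <- function(values, q) {
  if (length(values) == 0L) stop("empty-input error: no values")
  if (!all(is.finite(values))) stop("domain error: non-finite value")
  if (q < 0 || q > 1) stop("domain error: q must lie in [0, 1]")
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

#' Histogram-peak mode estimate
#'
#' The mode of a continuous signal is taken as the midpoint of the most
#' populated bin of an equal-width histogram with `ceiling(sqrt(n))` bins
#' over `[min, max]`; ties go to the lowest bin, and a degenerate range
#' (all values equal) returns that value.
#'
#' @param values Non-empty numeric vector, all finite.
#' @return The mode estimate.
#' @export
mode_estimate <- function(values) {
  if (length(values) == 0L) stop("empty-input error: no values")
  if (!all(is.finite(values))) stop("domain error: non-finite value")
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(lo)
  nbins <- ceiling(sqrt(length(values)))
  width <- (hi - lo) / nbins
  bin <- pmin(floor((values - lo) / width) + 1, nbins)
  counts <- tabulate(bin, nbins)
  best <- which.max(counts)   # which.max takes the first (lowest) maximum
  lo + (best - 0.5) * width
}

#' Compute the eleven statistical features of one sampled channel
#'
#' @param values Non-empty numeric vector of sampled amplitudes.
#' @return Named numeric vector with entries `X_Mean`, `X_Me`, `X_Mo`,
#'   `X_Q1`, `X_Q3`, `X_IQR`, `X_SD`, `X_beta1` (skewness), `X_beta2`
#'   (excess kurtosis), `X_Min`, `X_Max`.  A constant input has zero
#'   spread and, by convention, zero skewness and kurtosis.
#' @export
compute_features <- function(values) {
  if (length(values) == 0L) stop("empty-input error: no values")
  if (!all(is.finite(values))) stop("domain error: non-finite value")
  n <- length(values)
  mu <- mean(values)
  d <- values - mu
  m2 <- mean(d^2)
  if (m2 > 0) {
    beta1 <- mean(d^3) / m2^1.5
    beta2 <- mean(d^4) / m2^2 - 3
  } else {
    beta1 <- 0; beta2 <- 0
  }
  q1 <- quantile_linear(values, 0.25)
  q3 <- quantile_linear(values, 0.75)
  c(X_Mean = mu,
    X_Me = quantile_linear(values, 0.5),
    X_Mo = mode_estimate(values),
    X_Q1 = q1, X_Q3 = q3, X_IQR = q3 - q1,
    X_SD = if (n > 1) sqrt(sum(d^2) / (n - 1)) else 0,
    X_beta1 = beta1, X_beta2 = beta2,
    X_Min = min(values), X_Max = max(values))
}

#' Assemble the labeled feature matrix from sampled sets
#'
#' One row per (class, channel): the eleven statistics of that channel's
#' full sampled value sequence, in class-then-channel order.  For the
#' reference corpus shape (5 classes x 100 channels) this is the
#' 500 x 11 matrix fed to the classifiers.
#'
#' @param sample_sets List of [build_sample_set()] results (or any objects
#'   with `class_label` and a `values` matrix with channel columns).
#' @return Data frame of class `feature_matrix` with columns `class`,
#'   `channel` and the eleven features.
#' @export
build_feature_matrix <- function(sample_sets) {
  stopifnot(length(sample_sets) >= 1L)
  rows <- lapply(sample_sets, function(s) {
    v <- s$values
    stopifnot(is.matrix(v), ncol(v) >= 1L)
    ch <- colnames(v)
    if (is.null(ch)) ch <- sprintf("ch%03d", seq_len(ncol(v)))
    feats <- t(apply(v, 2, compute_features))
    data.frame(class = s$class_label, channel = ch, feats,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  key <- paste(df$class, df$channel, sep = "\r")
  if (anyDuplicated(key)) {
    stop("label-collision error: duplicate (class, channel) rows: ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  }
  names(df) <- feature_matrix_header()
  class(df) <- c("feature_matrix", "data.frame")
  df
}

# Numeric feature block of a feature matrix, as a plain matrix.
feature_values <- function(fm) {
  as.matrix(fm[, feature_names(), drop = FALSE])
}
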