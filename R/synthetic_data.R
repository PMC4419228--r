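# Synthetic EEG-like corpus generator.
#
# Each channel is an order-1 autoregressive series driven by skew-normal
# innovations whose standard deviation changes between time segments, so
# the signals are nonstationary in amplitude the way clinical EEG is and
# the optimum-allocation weights differ across segments.  The generator
# emulates the corpus layout (classes x channels x samples), not EEG
# physiology: there are no spectral peaks or spike-wave morphologies.

#' Specification of one synthetic signal class
#'
#' @param label Class label.
#' @param ar_coefficient AR(1) coefficient, `|phi| < 1` so each segment is
#'   stationary.
#' @param amplitude_scale Baseline innovation SD, > 0.
#' @param skew Skewness parameter of the innovations; 0 gives symmetric
#'   noise, larger values monotonically larger sample skewness.
#' @param segment_sd_multipliers Positive multipliers applied to the
#'   innovation SD inside each segment (recycled to the segment count).
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(label, ar_coefficient = 0.5, amplitude_scale = 1,
                       skew = 0, segment_sd_multipliers = 1) {
  if (abs(ar_coefficient) >= 1) stop("domain error: |ar_coefficient| must be < 1")
  if (amplitude_scale <= 0) stop("domain error: amplitude_scale must be > 0")
  if (any(!is.finite(segment_sd_multipliers)) ||
      any(segment_sd_multipliers <= 0)) {
    stop("domain error: segment_sd_multipliers must be finite and > 0")
  }
  structure(list(label = as.character(label),
                 ar_coefficient = ar_coefficient,
                 amplitude_scale = amplitude_scale,
                 skew = skew,
                 segment_sd_multipliers = segment_sd_multipliers),
            class = "class_spec")
}

# Standardized skew-normal innovations (Azzalini construction):
# delta |Z1| + sqrt(1 - delta^2) Z2, centered and scaled to mean 0, SD 1.
# The shape parameter monotonically controls the sample skewness.
rskewed <- function(n, skew) {
  delta <- skew / sqrt(1 + skew^2)
  z <- delta * abs(stats::rnorm(n)) + sqrt(1 - delta^2) * stats::rnorm(n)
  mu <- delta * sqrt(2 / pi)
  (z - mu) / sqrt(1 - mu^2)
}

#' Generate one synthetic class of channels
#'
#' Every channel is an AR(1) series `x_t = phi x_{t-1} + e_t` whose
#' innovations `e_t` are skew-normal with SD
#' `amplitude_scale * segment_sd_multipliers[i]` inside segment i (segment
#' boundaries from [segment_signal()]).
#'
#' @param spec A [class_spec()].
#' @param n_channels Number of channels.
#' @param n_samples Samples per channel, `>= k_segments`.
#' @param k_segments Number of variance segments.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A [class_dataset()].
#' @export
generate_class_signal <- function(spec, n_channels, n_samples,
                                  k_segments = 4L, seed = 1L) {
  stopifnot(inherits(spec, "class_spec"))
  n_channels <- as.integer(n_channels)
  n_samples <- as.integer(n_samples)
  k_segments <- as.integer(k_segments)
  if (n_channels < 1L) stop("domain error: n_channels must be >= 1")
  if (n_samples < k_segments || k_segments < 1L) {
    stop("domain error: need n_samples >= k_segments >= 1")
  }
  plan <- segment_signal(n_samples, k_segments)
  mult <- rep_len(spec$segment_sd_multipliers, k_segments)
  sd_t <- rep(spec$amplitude_scale * mult, plan$sizes)
  phi <- spec$ar_coefficient
  records <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_channels), function(ch) {
      e <- rskewed(n_samples, spec$skew) * sd_t
      x <- as.numeric(stats::filter(e, phi, method = "recursive"))
      signal_record(x, channel_id = sprintf("%s_ch%03d", spec$label, ch),
                    class_label = spec$label)
    })
  })
  class_dataset(records, class_label = spec$label)
}

#' Generate a multiclass benchmark corpus
#'
#' Builds `n_classes` class specs whose amplitude scale and skewness are
#' spaced by `separation` (separation 0 makes every class identical, so
#' any classifier should sit at chance).  With five classes the last one
#' is given a much larger amplitude, mimicking the visibly larger seizure
#' recordings of the reference corpus.  Per-segment SD multipliers are
#' rotated across classes so the optimum-allocation weights are
#' nontrivial.
#'
#' @param n_classes Number of classes, >= 2.
#' @param n_channels Channels per class.
#' @param n_samples Samples per channel.
#' @param seed Integer seed.
#' @param separation Spacing of amplitude scale and skew between
#'   consecutive classes (in baseline-SD units).
#' @param k_segments Number of variance segments per recording.
#' @return Named list of [class_dataset()] objects.
#' @export
generate_benchmark <- function(n_classes = 5L, n_channels = 20L,
                               n_samples = 1024L, seed = 1L,
                               separation = 1, k_segments = 4L) {
  specs <- benchmark_class_specs(n_classes, separation, k_segments)
  out <- lapply(seq_along(specs), function(i) {
    generate_class_signal(specs[[i]], n_channels, n_samples, k_segments,
                          seed = seed + 977L * i)
  })
  names(out) <- vapply(specs, function(s) s$label, character(1))
  out
}

# Class specs for generate_benchmark: amplitude scales and skews spaced
# by `separation`, per-segment SD multipliers rotated across classes.
benchmark_class_specs <- function(n_classes, separation, k_segments = 4L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("domain error: n_classes must be >= 2")
  base_mult <- c(1, 1.2, 0.85, 1.4)
  labels <- if (n_classes == 5L) {
    c("Z", "O", "N", "F", "S")
  } else {
    sprintf("C%02d", seq_len(n_classes))
  }
  lapply(seq_len(n_classes), function(i) {
    scale_i <- 1 + separation * (i - 1L)
    # seizure-like class: amplitude a few-fold above the ladder, as in
    # real ictal recordings; fades out with the rest of the separation
    if (n_classes == 5L && i == 5L) {
      scale_i <- scale_i * (1 + 1.5 * min(separation, 1))
    }
    rot <- ((seq_len(k_segments) + i - 2L) %% length(base_mult)) + 1L
    # damp the per-segment variance profile toward flat as separation -> 0
    # so separation 0 yields literally identical specs
    mult <- 1 + min(separation, 1) * (base_mult[rot] - 1)
    class_spec(labels[i],
               ar_coefficient = 0.5,
               amplitude_scale = scale_i,
               skew = separation * (i - 1L) / 2,
               segment_sd_multipliers = mult)
  })
}

#' Write a corpus to the on-disk directory layout
#'
#' One subdirectory per class under `root`, one ASCII channel file per
#' channel.
#'
#' @param corpus Named list of [class_dataset()] objects.
#' @param root Output root directory.
#' @return `root`, invisibly.
#' @export
write_corpus <- function(corpus, root) {
  for (ds in corpus) {
    d <- file.path(root, ds$class_label)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (rec in ds$records) {
      write_channel_file(rec, file.path(d, paste0(rec$channel_id, ".txt")))
    }
  }
  invisible(root)
}
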