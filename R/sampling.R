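# Segmentation and representative-sample selection.
#
# A recording of length L is split into k contiguous segments; each segment
# is treated as a finite population.  Under random sampling (RS) Cochran's
# formula with finite-population correction fixes a per-segment size; under
# optimum-allocation sampling (OS) the same formula applied to the whole
# recording fixes a class-level budget m that is then divided across
# segments proportional to N_i * sqrt(sum_j s_ij^2), favouring longer and
# more variable segments.

#' Partition a recording into k contiguous segments
#'
#' The first `k - 1` segments have size `floor(L / k)`; the remainder is
#' appended to the last segment, so 4097 points at k = 4 give sizes
#' (1024, 1024, 1024, 1025).
#'
#' @param L Total number of time points.
#' @param k Number of segments, `1 <= k <= L`.
#' @return An object of class `segmentation_plan` with fields
#'   `total_length`, `start` (1-based inclusive), `end` (inclusive) and
#'   `sizes`.
#' @export
segment_signal <- function(L, k) {
  L <- as.integer(L); k <- as.integer(k)
  if (is.na(L) || is.na(k) || k < 1L || k > L) {
    stop("invalid-partition error: need 1 <= k <= L (got k = ", k,
         ", L = ", L, ")")
  }
  base <- L %/% k
  sizes <- rep(base, k)
  sizes[k] <- L - (k - 1L) * base
  end <- cumsum(sizes)
  start <- end - sizes + 1L
  structure(list(total_length = L, start = start, end = end, sizes = sizes),
            class = "segmentation_plan")
}

#' Required sample size with finite-population correction
#'
#' Cochran's formula `SS = z^2 p (1 - p) / e^2` followed by the
#' finite-population correction `n = SS / (1 + (SS - 1) / Popu)`, rounded
#' up to the next integer.  At 99% confidence (z = 2.58), p = 0.5 and
#' e = 0.01 this yields 965 of 1024, 966 of 1025 and 3288 of 4097.
#'
#' @param Popu Population size (segment or recording length), >= 1.
#' @param z Standard normal quantile for the confidence level.
#' @param p Assumed population proportion, in (0, 1).
#' @param e Margin of error, > 0.
#' @return Integer sample size `n`, with `1 <= n <= Popu`.
#' @export
required_sample_size <- function(Popu, z = 2.58, p = 0.5, e = 0.01) {
  Popu <- as.integer(Popu)
  if (is.na(Popu) || Popu < 1L) stop("domain error: Popu must be >= 1")
  if (z <= 0) stop("domain error: z must be > 0")
  if (!(p > 0 && p < 1)) stop("domain error: p must lie in (0, 1)")
  if (e <= 0) stop("domain error: e must be > 0")
  ss <- z^2 * p * (1 - p) / e^2
  n <- as.integer(ceiling(ss / (1 + (ss - 1) / Popu)))
  min(n, Popu)
}

# Largest-remainder (Hamilton) apportionment of m among weights w,
# respecting caps; surplus from capped strata is redistributed among the
# uncapped ones by the same rule.
hamilton_allocate <- function(w, m, caps) {
  k <- length(w)
  n <- integer(k)
  capped <- w <= 0            # zero-weight strata receive nothing
  repeat {
    active <- which(!capped)
    remaining <- m - sum(n[capped])
    shares <- w[active] / sum(w[active]) * remaining
    alloc <- as.integer(floor(shares))
    short <- remaining - sum(alloc)
    if (short > 0L) {
      frac <- shares - alloc
      # ties broken toward the earlier segment
      ord <- order(-frac, seq_along(frac))
      alloc[ord[seq_len(short)]] <- alloc[ord[seq_len(short)]] + 1L
    }
    n[active] <- alloc
    over <- active[alloc > caps[active]]
    if (length(over) == 0L) break
    # cap the overfull strata and reallocate the rest from scratch
    n[over] <- caps[over]
    capped[over] <- TRUE
    if (all(capped)) break
  }
  n
}

#' Optimum allocation of a class-level sample budget across segments
#'
#' Divides the total budget `m` across the k segments proportional to
#' `w_i = N_i * sqrt(sum_j s_ij^2)`, where `s_ij^2` is the variance of
#' channel j within segment i, so longer and more variable segments
#' receive more of the budget.  Raw shares are converted to integers by
#' largest-remainder rounding that conserves `sum(n_i) = m` exactly; any
#' allocation exceeding its segment length is capped with the surplus
#' redistributed among the uncapped segments by the same rule.
#'
#' @param N Integer vector of segment sizes.
#' @param seg_channel_variances Matrix of per-segment (rows) per-channel
#'   (columns) variances, entries >= 0.
#' @param m Total sample budget, `m <= sum(N)`.
#' @return An object of class `allocation_result` with fields `n_i`
#'   (integer allocations), `weights`, `shares` (pre-rounding reals) and
#'   `m`.
#' @export
optimum_allocation <- function(N, seg_channel_variances, m) {
  N <- as.integer(N)
  m <- as.integer(m)
  s2 <- as.matrix(seg_channel_variances)
  if (nrow(s2) != length(N)) {
    stop("shape error: variance matrix needs one row per segment")
  }
  if (any(s2 < 0)) stop("domain error: variances must be >= 0")
  if (m > sum(N)) {
    stop("infeasible error: m = ", m, " exceeds total population ", sum(N))
  }
  w <- N * sqrt(rowSums(s2))
  if (all(w == 0)) {
    stop("degenerate-allocation error: all allocation weights are zero")
  }
  shares <- w / sum(w) * m
  n <- hamilton_allocate(w, m, caps = N)
  stopifnot(sum(n) == m, all(n >= 0L), all(n <= N))
  structure(list(n_i = n, weights = w, shares = shares, m = m),
            class = "allocation_result")
}

#' Draw sample time indices within each segment
#'
#' Selects `sizes[i]` time indices uniformly without replacement inside
#' segment i of `plan`; each returned list element is sorted ascending.
#' With a `seed` the draw is reproducible; with `seed = NULL` the current
#' RNG stream is used.
#'
#' @param plan A [segment_signal()] plan.
#' @param sizes Integer vector of per-segment sample counts.
#' @param seed Integer seed or `NULL`.
#' @return List of k sorted integer vectors of 1-based time indices.
#' @export
draw_sample_indices <- function(plan, sizes, seed = NULL) {
  stopifnot(inherits(plan, "segmentation_plan"))
  sizes <- as.integer(sizes)
  if (length(sizes) != length(plan$sizes)) {
    stop("shape error: one size per segment required")
  }
  if (any(sizes < 0L)) stop("domain error: sizes must be >= 0")
  if (any(sizes > plan$sizes)) {
    bad <- which(sizes > plan$sizes)[1L]
    stop("oversample error: segment ", bad, " holds ", plan$sizes[bad],
         " points but ", sizes[bad], " were requested")
  }
  draw <- function() {
    lapply(seq_along(sizes), function(i) {
      pool <- seq.int(plan$start[i], plan$end[i])
      sort(sample(pool, sizes[i], replace = FALSE))
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Build the sampled value set for one class
#'
#' Implements both selection schemes.  Under RS each segment is its own
#' finite population: the per-segment size comes from
#' [required_sample_size()] with `Popu` equal to the segment length.
#' Under OS the whole recording is the population: the class budget `m`
#' from [required_sample_size()] is split across segments by
#' [optimum_allocation()] using the per-segment per-channel variances
#' (unbiased, n - 1 denominator).  One set of time indices per segment is
#' shared by every channel of the class, preserving cross-channel time
#' alignment.
#'
#' @param dataset A [class_dataset()].
#' @param config A [run_config()]; `seed` may be overridden.
#' @param seed Integer seed for the index draw; defaults to `config$seed`.
#' @return An object of class `sample_set` with fields `class_label`,
#'   `scheme`, `plan`, `sizes` (per-segment counts), `indices`
#'   (per-segment sorted index vectors) and `values` (matrix,
#'   `sum(sizes)` rows x channels).
#' @export
build_sample_set <- function(dataset, config, seed = config$seed) {
  stopifnot(inherits(dataset, "class_dataset"), inherits(config, "run_config"))
  L <- dataset$n_samples_per_channel
  plan <- segment_signal(L, config$n_segments)
  X <- class_signal_matrix(dataset)
  if (config$scheme == "RS") {
    sizes <- vapply(plan$sizes, required_sample_size, integer(1),
                    z = config$confidence_z, p = config$proportion_p,
                    e = config$margin_e)
    alloc <- NULL
  } else {
    m <- required_sample_size(L, z = config$confidence_z,
                              p = config$proportion_p, e = config$margin_e)
    s2 <- t(vapply(seq_along(plan$sizes), function(i) {
      seg <- X[plan$start[i]:plan$end[i], , drop = FALSE]
      apply(seg, 2, stats::var)
    }, numeric(ncol(X))))
    s2 <- matrix(s2, nrow = length(plan$sizes))
    alloc <- optimum_allocation(plan$sizes, s2, m)
    sizes <- alloc$n_i
  }
  idx <- draw_sample_indices(plan, sizes, seed = seed)
  rows <- unlist(idx, use.names = FALSE)
  structure(
    list(class_label = dataset$class_label, scheme = config$scheme,
         plan = plan, sizes = as.integer(sizes), allocation = alloc,
         indices = idx, values = X[rows, , drop = FALSE]),
    class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set '%s' (%s): segments %s -> %d points x %d channels>\n",
              x$class_label, x$scheme,
              paste(x$sizes, collapse = "+"), sum(x$sizes), ncol(x$values)))
  invisible(x)
}

#' Realized per-segment sample sizes for a corpus
#'
#' Convenience summary in the layout of the published sample-size table:
#' one row per class, one column per segment plus the total.
#'
#' @param sample_sets List of [build_sample_set()] results.
#' @return Data frame with columns `class`, `Seg1..Segk`, `Total`.
#' @export
sample_size_table <- function(sample_sets) {
  k <- length(sample_sets[[1L]]$sizes)
  rows <- lapply(sample_sets, function(s) {
    stats::setNames(
      data.frame(s$class_label, t(s$sizes), sum(s$sizes)),
      c("class", paste0("Seg", seq_len(k)), "Total"))
  })
  do.call(rbind, rows)
}
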