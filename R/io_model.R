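# Domain types and disk I/O for the per-channel ASCII corpus layout
# (<root>/<class>/*.txt, one amplitude per line) and feature-matrix CSVs.

#' Canonical feature column names
#'
#' The eleven statistics computed per channel, in the fixed column order
#' used by every feature matrix the package reads or writes.
#'
#' @return Character vector of length 11.
#' @export
feature_names <- function() {
  c("X_Mean", "X_Me", "X_Mo", "X_Q1", "X_Q3", "X_IQR",
    "X_SD", "X_beta1", "X_beta2", "X_Min", "X_Max")
}

#' Construct a single-channel EEG record
#'
#' @param samples Numeric vector of amplitudes, one per time point.
#' @param channel_id Channel identifier (typically the source file name).
#' @param class_label Class the channel belongs to.
#' @param sampling_rate_hz Sampling rate in Hz; defaults to the 173.61 Hz
#'   of the reference corpus.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, channel_id, class_label,
                          sampling_rate_hz = 173.61) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("empty-input error: a signal record needs at least one sample")
  }
  if (!all(is.finite(samples))) {
    stop("domain error: non-finite amplitude in channel '", channel_id, "'")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("domain error: sampling_rate_hz must be > 0")
  }
  structure(
    list(channel_id = as.character(channel_id),
         class_label = as.character(class_label),
         samples = samples,
         sampling_rate_hz = sampling_rate_hz),
    class = "signal_record")
}

#' Construct a per-class dataset of equal-length channels
#'
#' @param records List of [signal_record()] objects sharing one class label
#'   and one sample count.
#' @param class_label Class label; defaults to the label of the first record.
#' @return An object of class `class_dataset` with fields `class_label`,
#'   `records` and `n_samples_per_channel`.
#' @export
class_dataset <- function(records, class_label = NULL) {
  if (length(records) == 0L) {
    stop("empty-input error: a class dataset needs at least one record")
  }
  stopifnot(all(vapply(records, inherits, logical(1), "signal_record")))
  if (is.null(class_label)) class_label <- records[[1L]]$class_label
  labs <- vapply(records, function(r) r$class_label, character(1))
  if (!all(labs == class_label)) {
    stop("domain error: records carry mixed class labels: ",
         paste(unique(labs), collapse = ", "))
  }
  lens <- vapply(records, function(r) length(r$samples), integer(1))
  if (length(unique(lens)) != 1L) {
    bad <- vapply(records, function(r) r$channel_id, character(1))
    stop("ragged-data error: channels differ in length (",
         paste(sprintf("%s=%d", bad, lens), collapse = ", "), ")")
  }
  structure(
    list(class_label = as.character(class_label),
         records = records,
         n_samples_per_channel = lens[[1L]]),
    class = "class_dataset")
}

#' @export
print.class_dataset <- function(x, ...) {
  cat(sprintf("<class_dataset '%s': %d channels x %d samples>\n",
              x$class_label, length(x$records), x$n_samples_per_channel))
  invisible(x)
}

# Matrix view of a class: samples x channels, channel ids as colnames.
class_signal_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "class_dataset"))
  m <- vapply(dataset$records, function(r) r$samples,
              numeric(dataset$n_samples_per_channel))
  m <- matrix(m, nrow = dataset$n_samples_per_channel)
  colnames(m) <- vapply(dataset$records, function(r) r$channel_id, character(1))
  m
}

#' Read one channel file
#'
#' Parses an ASCII channel file with one amplitude per line.  Blank lines
#' and surrounding whitespace are tolerated; anything else that does not
#' parse as a number is a format error naming the offending line.
#'
#' @param path Path to the channel file.
#' @param channel_id Channel identifier; defaults to the file name.
#' @param class_label Class label to attach.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return A [signal_record()].
#' @export
read_channel_file <- function(path, channel_id = basename(path),
                              class_label = "unknown",
                              sampling_rate_hz = 173.61) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed)
  if (!any(keep)) {
    stop("empty-input error: no samples in ", path)
  }
  vals <- suppressWarnings(as.numeric(trimmed[keep]))
  if (anyNA(vals)) {
    bad_line <- which(keep)[which(is.na(vals))[1L]]
    stop(sprintf("format error: line %d of %s is not a number: '%s'",
                 bad_line, path, lines[bad_line]))
  }
  signal_record(vals, channel_id = channel_id, class_label = class_label,
                sampling_rate_hz = sampling_rate_hz)
}

#' Read a class directory of channel files
#'
#' Reads every `*.txt` file in `dir` (sorted by file name) as one channel
#' of a single class.  All channels must have the same length.
#'
#' @param dir Directory holding one ASCII channel file per channel.
#' @param class_label Class label; defaults to the directory name.
#' @param pattern Regular expression selecting channel files.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return A [class_dataset()].
#' @export
read_class_directory <- function(dir, class_label = basename(dir),
                                 pattern = "\\.txt$",
                                 sampling_rate_hz = 173.61) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) {
    stop("empty-input error: no channel files in ", dir)
  }
  records <- lapply(files, function(f) {
    read_channel_file(f, channel_id = basename(f), class_label = class_label,
                      sampling_rate_hz = sampling_rate_hz)
  })
  class_dataset(records, class_label = class_label)
}

#' Read a whole corpus
#'
#' Expects the layout `<root>/<class_label>/*.txt` and returns one
#' [class_dataset()] per subdirectory, sorted by class label.
#'
#' @param root Corpus root directory.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Named list of `class_dataset` objects.
#' @export
read_corpus <- function(root, sampling_rate_hz = 173.61) {
  if (!dir.exists(root)) stop("directory not found: ", root)
  dirs <- sort(list.dirs(root, recursive = FALSE))
  if (length(dirs) == 0L) stop("empty-input error: no class directories in ", root)
  out <- lapply(dirs, read_class_directory, sampling_rate_hz = sampling_rate_hz)
  names(out) <- vapply(out, function(d) d$class_label, character(1))
  out
}

#' Write a channel file
#'
#' @param record A [signal_record()].
#' @param path Output file path.
#' @export
write_channel_file <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  writeLines(sprintf("%.15g", record$samples), path)
  invisible(path)
}

feature_matrix_header <- function() c("class", "channel", feature_names())

#' Write a feature matrix as CSV
#'
#' The on-disk schema is a CSV with the fixed header
#' `class,channel,X_Mean,...,X_Max` so that reports are diffable.
#'
#' @param matrix A feature matrix data frame as produced by
#'   [build_feature_matrix()].
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(matrix, path) {
  hdr <- feature_matrix_header()
  if (!identical(names(matrix), hdr)) {
    stop("schema error: feature matrix columns must be exactly ",
         paste(hdr, collapse = ","))
  }
  out <- matrix
  for (nm in feature_names()) out[[nm]] <- sprintf("%.15g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix CSV
#'
#' @param path CSV path written by [write_feature_matrix()].
#' @return A feature matrix data frame; a valid header with zero rows
#'   yields an empty matrix.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(class = "character",
                                       channel = "character"))
  hdr <- feature_matrix_header()
  if (!identical(names(df), hdr)) {
    missing <- setdiff(hdr, names(df))
    extra <- setdiff(names(df), hdr)
    stop("schema error: ",
         if (length(missing)) paste0("missing columns: ",
                                     paste(missing, collapse = ", ")) else "",
         if (length(missing) && length(extra)) "; " else "",
         if (length(extra)) paste0("unexpected columns: ",
                                   paste(extra, collapse = ", ")) else "")
  }
  for (nm in feature_names()) df[[nm]] <- as.numeric(df[[nm]])
  class(df) <- c("feature_matrix", "data.frame")
  df
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline: segmentation, sampling design,
#' classifier choice and hyperparameters, cross-validation and repetition
#' protocol.
#'
#' @param n_segments Number of non-overlapping time segments per recording.
#' @param scheme Sampling scheme, `"RS"` (per-segment random sampling) or
#'   `"OS"` (class-level budget split by optimum allocation).
#' @param confidence_z Standard normal quantile for the confidence level
#'   (2.58 for 99%).
#' @param proportion_p Assumed population proportion in Cochran's formula.
#' @param margin_e Desired margin of error.
#' @param classifier One of `"knn"`, `"mlr"`, `"svm"`.
#' @param n_folds Cross-validation folds.
#' @param n_repetitions Number of independent sampling repetitions.
#' @param seed Base random seed.
#' @param knn_k Neighbourhood size; `NA` selects k in `1..knn_k_max` by
#'   cross-validation on each training fold.
#' @param knn_k_max Upper bound of the k search range.
#' @param mlr_lambda Ridge penalty on the non-intercept coefficients.
#' @param svm_cost Soft-margin cost C of the binary RBF SVMs.
#' @param svm_gamma RBF kernel width; `NA` means 1 / (number of features).
#' @param normalization Per-feature normalization fitted on the training
#'   fold: `"minmax"`, `"zscore"` or `"none"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_segments = 4L, scheme = c("RS", "OS"),
                       confidence_z = 2.58, proportion_p = 0.5,
                       margin_e = 0.01,
                       classifier = c("knn", "mlr", "svm"),
                       n_folds = 10L, n_repetitions = 20L, seed = 1L,
                       knn_k = 1L, knn_k_max = 30L,
                       mlr_lambda = 1e-8, svm_cost = 1, svm_gamma = NA_real_,
                       normalization = c("minmax", "zscore", "none")) {
  scheme <- match.arg(toupper(scheme[1L]), c("RS", "OS"))
  classifier <- match.arg(classifier)
  normalization <- match.arg(normalization)
  cfg <- list(n_segments = as.integer(n_segments), scheme = scheme,
              confidence_z = confidence_z, proportion_p = proportion_p,
              margin_e = margin_e, classifier = classifier,
              n_folds = as.integer(n_folds),
              n_repetitions = as.integer(n_repetitions),
              seed = as.integer(seed),
              knn_k = if (is.na(knn_k)) NA_integer_ else as.integer(knn_k),
              knn_k_max = as.integer(knn_k_max),
              mlr_lambda = mlr_lambda, svm_cost = svm_cost,
              svm_gamma = svm_gamma, normalization = normalization)
  if (cfg$n_segments < 1L) stop("domain error: n_segments must be >= 1")
  if (!(cfg$proportion_p > 0 && cfg$proportion_p < 1)) {
    stop("domain error: proportion_p must lie in (0, 1)")
  }
  if (cfg$margin_e <= 0) stop("domain error: margin_e must be > 0")
  if (cfg$confidence_z <= 0) stop("domain error: confidence_z must be > 0")
  if (cfg$n_folds < 2L) stop("domain error: n_folds must be >= 2")
  if (cfg$n_repetitions < 1L) stop("domain error: n_repetitions must be >= 1")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file is a flat key-value mapping of [run_config()] argument names;
#' entries in `overrides` (e.g. parsed command-line flags) take precedence
#' over file values, which take precedence over the defaults.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides Named list of values overriding the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (!is.list(vals)) stop("format error: config must be a key-value mapping")
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("schema error: unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}
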