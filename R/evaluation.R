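# Stratified cross-validation, the multiclass metric panel, and the
# repeated-sampling experiment protocol.
#
# Per repetition the per-fold predictions are pooled into one confusion
# matrix before metrics are computed; metrics are then averaged (with
# standard errors) across repetitions.  Per-class "accuracy" is reported
# as that class's recall, and overall values are unweighted macro means —
# the conventions under which the published per-class/overall tables are
# internally consistent.

#' Stratified k-fold assignment
#'
#' Shuffles each class independently (seeded) and deals its rows
#' round-robin into folds, so per-class counts across folds differ by at
#' most one.  500 rows in 5 balanced classes at 10 folds give exactly
#' 50-row folds with 10 rows per class.
#'
#' @param labels Class label per row.
#' @param n_folds Number of folds; every class must have at least
#'   `n_folds` members.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_kfold <- function(labels, n_folds, seed = 1L) {
  labels <- as.character(labels)
  n_folds <- as.integer(n_folds)
  cnt <- table(labels)
  if (any(cnt < n_folds)) {
    small <- names(cnt)[cnt < n_folds]
    stop("stratification error: class(es) smaller than n_folds: ",
         paste(small, collapse = ", "))
  }
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in names(cnt)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# Rank-based ROC area with ties counted half: P(score+ > score-) + P(=)/2.
roc_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix and the full multiclass metric panel
#'
#' Computes, per class one-vs-rest: TPR (= recall = per-class accuracy),
#' FAR (false alarm rate, `FP / (FP + TN)`), precision, F-measure — all in
#' percent — and ROC area (rank statistic, ties counted half).  Overall
#' values are unweighted macro means.  Also: Cohen's kappa on the pooled
#' confusion matrix (scale-free, in `[-1, 1]`), and the classification MAE
#' `mean(|score - onehot|)` over all instance-class cells.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param scores Optional instance x class score matrix (probabilities or
#'   vote shares) with columns named by class; enables MAE and ROC area.
#' @param labels Class order; defaults to the sorted union of the labels
#'   seen.  A label absent from both truth and prediction is dropped with
#'   a warning.
#' @return A `metrics_report`: list with `confusion`, `per_class` (data
#'   frame), `overall` (named numeric: macro TPR/FAR/precision/recall/
#'   F-value/accuracy in percent, kappa, MAE, macro AUC).
#' @export
confusion_and_metrics <- function(y_true, y_pred, scores = NULL,
                                  labels = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("shape error: length mismatch")
  seen <- sort(unique(c(y_true, y_pred)))
  if (is.null(labels)) {
    labels <- seen
  } else {
    dead <- setdiff(labels, seen)
    if (length(dead)) {
      warning("dropping class(es) absent from truth and predictions: ",
              paste(dead, collapse = ", "))
      labels <- setdiff(labels, dead)
    }
  }
  cm <- table(factor(y_true, levels = labels),
              factor(y_pred, levels = labels))
  cm <- matrix(as.integer(cm), nrow = length(labels),
               dimnames = list(true = labels, predicted = labels))
  total <- sum(cm)
  per <- lapply(seq_along(labels), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
    far <- if (fp + tn > 0) fp / (fp + tn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
    auc <- if (!is.null(scores)) {
      roc_auc(scores[, labels[i]], y_true == labels[i])
    } else NA_real_
    data.frame(class = labels[i], TPR = 100 * tpr, FAR = 100 * far,
               precision = 100 * prec, recall = 100 * tpr,
               F_value = 100 * f, accuracy = 100 * tpr, AUC = auc,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1
  mae <- if (!is.null(scores)) {
    onehot <- outer(y_true, labels, "==") + 0
    mean(abs(scores[, labels, drop = FALSE] - onehot))
  } else NA_real_
  overall <- c(TPR = mean(per$TPR), FAR = mean(per$FAR),
               precision = mean(per$precision), recall = mean(per$recall),
               F_value = mean(per$F_value), accuracy = mean(per$accuracy),
               kappa = kappa, MAE = mae, AUC = mean(per$AUC))
  structure(list(confusion = cm, per_class = per, overall = overall),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 1, ...) {
  cat("Confusion matrix (rows = true):\n")
  print(x$confusion)
  cat("\nPer-class metrics (%):\n")
  print(format(x$per_class, digits = digits + 2), row.names = FALSE)
  cat(sprintf("\nOverall: accuracy %.*f%%  kappa %.3f  MAE %.3f  AUC %.3f\n",
              digits, x$overall[["accuracy"]], x$overall[["kappa"]],
              x$overall[["MAE"]], x$overall[["AUC"]]))
  invisible(x)
}

# One stratified-CV pass over a feature matrix; returns pooled truth,
# predictions and scores.
cross_validate <- function(fm, config, cv_seed) {
  X <- feature_values(fm)
  y <- fm$class
  fold <- stratified_kfold(y, config$n_folds, seed = cv_seed)
  labels <- sort(unique(y))
  pred <- character(length(y))
  scores <- matrix(NA_real_, length(y), length(labels),
                   dimnames = list(NULL, labels))
  for (f in sort(unique(fold))) {
    te <- fold == f
    nrm <- fit_normalizer(X[!te, , drop = FALSE], config$normalization)
    trX <- apply_normalizer(nrm, X[!te, , drop = FALSE], clip = FALSE)
    teX <- apply_normalizer(nrm, X[te, , drop = FALSE])
    try_y <- y[!te]
    res <- switch(config$classifier,
      knn = {
        k <- config$knn_k
        if (is.na(k)) {
          k <- select_k(trX, try_y, k_max = config$knn_k_max,
                        folds = config$n_folds, seed = cv_seed)
        }
        knn_fit_predict(trX, try_y, teX, k = k, normalize = FALSE,
                        labels = labels)
      },
      mlr = {
        model <- mlr_fit(trX, try_y, lambda = config$mlr_lambda)
        list(labels = mlr_predict(model, teX),
             scores = mlr_predict_proba(model, teX))
      },
      svm = {
        gamma <- config$svm_gamma
        if (is.na(gamma)) gamma <- 1 / ncol(X)
        svm_fit_predict(trX, try_y, teX, cost = config$svm_cost,
                        gamma = gamma)
      })
    pred[te] <- res$labels
    scores[te, colnames(res$scores)] <- res$scores
  }
  list(y_true = y, y_pred = pred, scores = scores, fold = fold)
}

#' Run the full repeated-sampling experiment
#'
#' For each repetition r (seed = base seed + r - 1): draw fresh sample
#' sets for every class, extract the feature matrix, run stratified
#' n-fold cross-validation with the configured classifier, pool the fold
#' predictions into one confusion matrix and compute the metric panel.
#' The final report carries the mean and standard error of every overall
#' metric across repetitions, plus per-repetition reports and the
#' realized sample sizes.
#'
#' @param corpus List of [class_dataset()] objects (one per class).
#' @param config A [run_config()].
#' @return An `experiment_report` with fields `overall_mean`,
#'   `overall_se`, `per_class_mean`, `repetitions` (list of
#'   `metrics_report`), `sample_sizes`, `config` and `seeds`.
#' @export
run_experiment <- function(corpus, config) {
  stopifnot(length(corpus) >= 1L, inherits(config, "run_config"))
  rep_seeds <- config$seed + seq_len(config$n_repetitions) - 1L
  reps <- vector("list", config$n_repetitions)
  size_tab <- NULL
  for (r in seq_len(config$n_repetitions)) {
    sets <- lapply(seq_along(corpus), function(ci) {
      # distinct per-class draw seeds within the repetition
      build_sample_set(corpus[[ci]], config,
                       seed = rep_seeds[r] + 131L * ci)
    })
    if (r == 1L) size_tab <- sample_size_table(sets)
    fm <- build_feature_matrix(sets)
    cv <- cross_validate(fm, config, cv_seed = rep_seeds[r])
    reps[[r]] <- confusion_and_metrics(cv$y_true, cv$y_pred, cv$scores)
  }
  ov <- do.call(rbind, lapply(reps, function(m) m$overall))
  pc <- Reduce(`+`, lapply(reps, function(m) {
    as.matrix(m$per_class[, -1L])
  })) / length(reps)
  pc <- data.frame(class = reps[[1L]]$per_class$class, pc,
                   stringsAsFactors = FALSE)
  se <- apply(ov, 2, function(v) {
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  })
  structure(
    list(overall_mean = colMeans(ov), overall_se = se,
         per_class_mean = pc, repetitions = reps,
         sample_sizes = size_tab, config = config, seeds = rep_seeds),
    class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<experiment_report: %s + %s, %d repetition(s), %d-fold CV>\n",
              cfg$scheme, cfg$classifier, cfg$n_repetitions, cfg$n_folds))
  cat("\nRealized sample sizes (repetition 1):\n")
  print(x$sample_sizes, row.names = FALSE)
  cat("\nPer-class means over repetitions (%):\n")
  print(format(x$per_class_mean, digits = 3), row.names = FALSE)
  cat("\nOverall mean (SE) over repetitions:\n")
  for (nm in names(x$overall_mean)) {
    cat(sprintf("  %-9s %8.3f (%.3f)\n", nm, x$overall_mean[[nm]],
                x$overall_se[[nm]]))
  }
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Emits `report.json` (config echo, seeds, realized sample sizes,
#' overall mean/SE, per-class means), `report.csv` (per-class means) and
#' one confusion-matrix CSV per repetition.
#'
#' @param report An [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_class_mean,
                   file.path(dir, "report.csv"), row.names = FALSE)
  for (r in seq_along(report$repetitions)) {
    utils::write.csv(report$repetitions[[r]]$confusion,
                     file.path(dir, sprintf("confusion_rep%02d.csv", r)))
  }
  payload <- list(
    config = unclass(report$config),
    seeds = report$seeds,
    sample_sizes = report$sample_sizes,
    overall_mean = as.list(report$overall_mean),
    overall_se = as.list(report$overall_se),
    per_class_mean = report$per_class_mean)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
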