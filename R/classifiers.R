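# The three detection back ends.
#
# k-NN: Euclidean distance on (optionally min-max normalized) features,
# fully deterministic tie rules.  MLR: multinomial logistic regression
# with the last class as reference and a ridge penalty on non-intercept
# coefficients, minimized by BFGS with the analytic gradient.  SVM:
# one-vs-one decomposition into K(K-1)/2 binary soft-margin RBF machines
# (binary solver delegated to e1071/libsvm) combined by pairwise voting.

# ---- feature normalization (fitted on training rows only) ----

#' Fit a per-feature normalizer on training rows
#'
#' Min-max scaling maps each training feature to `[0, 1]`; test values are
#' transformed with the training bounds and clipped to the guard range
#' `[-0.5, 1.5]` so an out-of-range test point cannot dominate distances.
#' Z-score scaling centers and scales by training mean and SD.  Constant
#' features map to 0.
#'
#' @param train_X Numeric training matrix (rows = instances).
#' @param method `"minmax"`, `"zscore"` or `"none"`.
#' @return A `feature_normalizer` to pass to [apply_normalizer()].
#' @export
fit_normalizer <- function(train_X, method = c("minmax", "zscore", "none")) {
  method <- match.arg(method)
  train_X <- as.matrix(train_X)
  prm <- switch(method,
    minmax = list(lo = apply(train_X, 2, min), hi = apply(train_X, 2, max)),
    zscore = list(mu = colMeans(train_X), sd = apply(train_X, 2, stats::sd)),
    none = list())
  structure(list(method = method, prm = prm), class = "feature_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param norm A [fit_normalizer()] result.
#' @param X Numeric matrix with the same columns as the training matrix.
#' @param clip For min-max, clip transformed values to `[-0.5, 1.5]`.
#' @return Transformed matrix.
#' @export
apply_normalizer <- function(norm, X, clip = TRUE) {
  stopifnot(inherits(norm, "feature_normalizer"))
  X <- as.matrix(X)
  switch(norm$method,
    none = X,
    minmax = {
      rng <- norm$prm$hi - norm$prm$lo
      rng[rng == 0] <- 1      # constant feature -> 0 everywhere
      Z <- sweep(sweep(X, 2, norm$prm$lo), 2, rng, "/")
      if (clip) Z <- pmin(pmax(Z, -0.5), 1.5)
      Z
    },
    zscore = {
      s <- norm$prm$sd
      s[s == 0] <- 1
      sweep(sweep(X, 2, norm$prm$mu), 2, s, "/")
    })
}

# ---- k-nearest neighbours ----

#' k-NN classification with majority vote
#'
#' Labels each test row by the majority class among its k nearest training
#' rows under Euclidean distance.  Ties are fully deterministic: a vote
#' tie goes to the single nearest neighbour's label, and a distance tie
#' goes to the lower training-row index.  The per-class score is the
#' fraction of the k neighbours carrying that class.
#'
#' @param train_X,train_y Training feature matrix and labels.
#' @param test_X Test feature matrix.
#' @param k Neighbourhood size, `1 <= k <= nrow(train_X)`.
#' @param normalize Fit min-max normalization on the training rows and
#'   apply it to both sets (set `FALSE` when the caller normalizes).
#' @param labels Class label order for the score columns; defaults to
#'   `sort(unique(train_y))`.
#' @return List with `labels` (predicted) and `scores`
#'   (rows x classes, rows sum to 1).
#' @export
knn_fit_predict <- function(train_X, train_y, test_X, k,
                            normalize = TRUE, labels = NULL) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  train_y <- as.character(train_y)
  k <- as.integer(k)
  if (k < 1L || k > nrow(train_X)) {
    stop("parameter error: k must lie in 1..", nrow(train_X))
  }
  if (ncol(train_X) != ncol(test_X)) stop("shape error: feature mismatch")
  if (is.null(labels)) labels <- sort(unique(train_y))
  if (normalize) {
    nrm <- fit_normalizer(train_X, "minmax")
    train_X <- apply_normalizer(nrm, train_X, clip = FALSE)
    test_X <- apply_normalizer(nrm, test_X)
  }
  # squared Euclidean distances, test rows x train rows
  d2 <- outer(rowSums(test_X^2), rowSums(train_X^2), "+") -
    2 * tcrossprod(test_X, train_X)
  scores <- matrix(0, nrow(test_X), length(labels),
                   dimnames = list(NULL, labels))
  pred <- character(nrow(test_X))
  for (i in seq_len(nrow(test_X))) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))  # distance tie -> lower index
    nb <- ord[seq_len(k)]
    votes <- table(factor(train_y[nb], levels = labels))
    scores[i, ] <- as.numeric(votes) / k
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1L) top else train_y[nb[1L]]
  }
  list(labels = pred, scores = scores)
}

#' Select k by cross-validated error
#'
#' Evaluates every `k` in `1..k_max` by stratified cross-validation on the
#' training data and returns the k with the lowest error; ties go to the
#' smallest k.
#'
#' @param train_X,train_y Training features and labels.
#' @param k_max Largest k to try.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold shuffle.
#' @return The selected integer k.
#' @export
select_k <- function(train_X, train_y, k_max = 30L, folds = 10L, seed = 1L) {
  train_X <- as.matrix(train_X)
  train_y <- as.character(train_y)
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("parameter error: k_max must be >= 1")
  folds <- min(as.integer(folds), min(table(train_y)))
  if (folds < 2L) {
    fold_id <- rep(1:2, length.out = nrow(train_X))  # leave-half-out fallback
  } else {
    fold_id <- stratified_kfold(train_y, folds, seed)
  }
  max_train <- min(vapply(unique(fold_id), function(f) sum(fold_id != f),
                          integer(1)))
  if (k_max > max_train) {
    stop("parameter error: k_max = ", k_max,
         " exceeds the largest usable neighbourhood ", max_train)
  }
  errs <- vapply(seq_len(k_max), function(k) {
    wrong <- 0L
    for (f in unique(fold_id)) {
      te <- fold_id == f
      p <- knn_fit_predict(train_X[!te, , drop = FALSE], train_y[!te],
                           train_X[te, , drop = FALSE], k)
      wrong <- wrong + sum(p$labels != train_y[te])
    }
    wrong
  }, integer(1))
  which.min(errs)  # first minimum = smallest tied k
}

# ---- multinomial logistic regression with ridge estimator ----

# Class-probability matrix for coefficient matrix B ((m+1) x (K-1),
# first row = intercept) with the last class as reference.
mlr_proba <- function(B, X1, K) {
  eta <- cbind(X1 %*% B, 0)               # n x K, reference column 0
  eta <- eta - apply(eta, 1, max)         # guard against overflow
  P <- exp(eta)
  P / rowSums(P)
}

#' Ridge-penalized negative multinomial log-likelihood and gradient
#'
#' The objective minimized by [mlr_fit()]: the negative log-likelihood of
#' the multinomial logit probabilities (last class as reference) plus
#' `lambda * sum(B[-intercept]^2)`.  Exposed so the analytic gradient can
#' be checked against finite differences.
#'
#' @param b Coefficient vector, `(ncol(X) + 1) * (K - 1)` long, column-major.
#' @param X Feature matrix (no intercept column).
#' @param Y One-hot matrix, n x K.
#' @param lambda Ridge penalty, >= 0.
#' @return `mlr_objective` returns the scalar loss; `mlr_gradient` its
#'   gradient with respect to `b`.
#' @export
mlr_objective <- function(b, X, Y, lambda) {
  K <- ncol(Y)
  X1 <- cbind(1, X)
  B <- matrix(b, ncol = K - 1L)
  P <- mlr_proba(B, X1, K)
  ll <- sum(Y * log(pmax(P, .Machine$double.xmin)))
  -ll + lambda * sum(B[-1L, ]^2)
}

#' @rdname mlr_objective
#' @export
mlr_gradient <- function(b, X, Y, lambda) {
  K <- ncol(Y)
  X1 <- cbind(1, X)
  B <- matrix(b, ncol = K - 1L)
  P <- mlr_proba(B, X1, K)
  G <- crossprod(X1, P[, -K, drop = FALSE] - Y[, -K, drop = FALSE])
  pen <- 2 * lambda * B
  pen[1L, ] <- 0                          # intercept unpenalized
  as.numeric(G + pen)
}

#' Fit multinomial logistic regression with a ridge estimator
#'
#' Minimizes the ridge-penalized negative multinomial log-likelihood over
#' the `(m + 1) x (K - 1)` coefficient matrix (intercept row unpenalized,
#' last class as reference) with the BFGS quasi-Newton method and the
#' analytic gradient.  A loss trace across accepted iterations is kept on
#' the model.
#'
#' @param X Feature matrix, rows = instances.
#' @param y Class labels; at least two classes must be present.
#' @param lambda Ridge penalty on non-intercept coefficients.
#' @param tolerance Convergence tolerance on the gradient max-norm.
#' @param max_iter Iteration budget for the optimizer.
#' @return An `mlr_model` with fields `B` (coefficients), `labels`,
#'   `lambda`, `loss_trace`, `grad_norm` and `converged`.
#' @export
mlr_fit <- function(X, y, lambda = 1e-8, tolerance = 1e-3, max_iter = 1000L) {
  X <- as.matrix(X)
  y <- as.character(y)
  labels <- sort(unique(y))
  K <- length(labels)
  if (K < 2L) stop("domain error: at least two classes required")
  if (!all(is.finite(X))) stop("domain error: non-finite feature value")
  Y <- outer(y, labels, "==") + 0
  b0 <- numeric((ncol(X) + 1L) * (K - 1L))
  trace_env <- new.env()
  trace_env$loss <- mlr_objective(b0, X, Y, lambda)
  fn <- function(b) mlr_objective(b, X, Y, lambda)
  gr <- function(b) {
    # optim's BFGS evaluates the gradient once per accepted iterate, so
    # logging here records the loss trace across iterations
    trace_env$loss <- c(trace_env$loss, mlr_objective(b, X, Y, lambda))
    mlr_gradient(b, X, Y, lambda)
  }
  fit <- stats::optim(b0, fn, gr, method = "BFGS",
                      control = list(maxit = as.integer(max_iter),
                                     reltol = 1e-12))
  gnorm <- max(abs(mlr_gradient(fit$par, X, Y, lambda)))
  converged <- gnorm <= tolerance
  if (fit$convergence != 0L && !converged) {
    warning("convergence warning: optimizer stopped after ", max_iter,
            " iterations with gradient max-norm ", format(gnorm))
  }
  structure(
    list(B = matrix(fit$par, ncol = K - 1L), labels = labels,
         lambda = lambda, loss = fit$value,
         loss_trace = trace_env$loss, grad_norm = gnorm,
         converged = converged),
    class = "mlr_model")
}

#' Predicted class probabilities from a fitted MLR model
#'
#' @param model An [mlr_fit()] result.
#' @param X Feature matrix with the training column count.
#' @return Matrix of probabilities, one column per class in `model$labels`;
#'   rows sum to 1.
#' @export
mlr_predict_proba <- function(model, X) {
  stopifnot(inherits(model, "mlr_model"))
  X <- as.matrix(X)
  if (ncol(X) + 1L != nrow(model$B)) {
    stop("shape error: model expects ", nrow(model$B) - 1L, " features, got ",
         ncol(X))
  }
  P <- mlr_proba(model$B, cbind(1, X), length(model$labels))
  colnames(P) <- model$labels
  P
}

#' Predicted labels from a fitted MLR model
#'
#' @inheritParams mlr_predict_proba
#' @return Character vector of predicted labels (argmax probability, ties
#'   to the earlier label).
#' @export
mlr_predict <- function(model, X) {
  P <- mlr_predict_proba(model, X)
  model$labels[apply(P, 1, which.max)]
}

# ---- one-vs-one RBF SVM ----

#' One-vs-one RBF SVM with pairwise voting
#'
#' Fits one binary soft-margin RBF SVM per unordered class pair —
#' `K(K-1)/2` machines — and labels each test row by the class with the
#' most pairwise votes; argmax ties go to the class earliest in label
#' order.  The score for a class is its vote share `votes / (K - 1)`.
#' The binary quadratic-programming solver is delegated to
#' [e1071::svm()] (libsvm); the decomposition, voting rule and defaults
#' are implemented here.
#'
#' @param train_X,train_y Training features and labels (>= 2 classes).
#' @param test_X Test features.
#' @param cost Soft-margin cost C > 0.
#' @param gamma RBF kernel width; default `1 / ncol(train_X)`.
#' @param normalize Fit min-max normalization on the training rows.
#' @return List with `labels`, `scores` (vote shares) and `votes`
#'   (integer vote counts).
#' @export
svm_fit_predict <- function(train_X, train_y, test_X,
                            cost = 1, gamma = 1 / ncol(train_X),
                            normalize = FALSE) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  train_y <- as.character(train_y)
  if (cost <= 0 || gamma <= 0) stop("domain error: cost and gamma must be > 0")
  labels <- sort(unique(train_y))
  K <- length(labels)
  if (K < 2L) stop("domain error: at least two classes required")
  if (normalize) {
    nrm <- fit_normalizer(train_X, "minmax")
    train_X <- apply_normalizer(nrm, train_X, clip = FALSE)
    test_X <- apply_normalizer(nrm, test_X)
  }
  votes <- matrix(0L, nrow(test_X), K, dimnames = list(NULL, labels))
  for (a in seq_len(K - 1L)) {
    for (b in seq.int(a + 1L, K)) {
      sel <- train_y %in% labels[c(a, b)]
      if (length(unique(train_y[sel])) < 2L) {
        stop("degenerate-pair error: pair (", labels[a], ", ", labels[b],
             ") lacks a class in the training data")
      }
      fit <- e1071::svm(train_X[sel, , drop = FALSE],
                        factor(train_y[sel], levels = labels[c(a, b)]),
                        type = "C-classification", kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      p <- as.character(predict(fit, test_X))
      votes[, a] <- votes[, a] + (p == labels[a])
      votes[, b] <- votes[, b] + (p == labels[b])
    }
  }
  pred <- labels[apply(votes, 1, which.max)]  # ties -> earliest label
  list(labels = pred, scores = votes / (K - 1L), votes = votes)
}
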