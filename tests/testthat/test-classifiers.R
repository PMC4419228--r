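test_that("k-NN labels by majority vote with deterministic tie rules", {
  r1 <- knn_fit_predict(matrix(c(0, 1)), c("A", "B"), matrix(0.2), k = 1)
  expect_equal(r1$labels, "A")
  expect_equal(r1$scores[1, ], c(A = 1, B = 0))

  # query equal to a training point
  r2 <- knn_fit_predict(matrix(c(0, 1)), c("A", "B"), matrix(1), k = 1)
  expect_equal(r2$labels, "B")

  # three neighbours, two B: majority B with score 2/3
  r3 <- knn_fit_predict(matrix(c(0, 0.9, 1.1)), c("A", "B", "B"),
                        matrix(1.0), k = 3)
  expect_equal(r3$labels, "B")
  expect_equal(unname(r3$scores[1, "B"]), 2 / 3)

  # vote tie resolves to the single nearest neighbour's label
  r4 <- knn_fit_predict(matrix(c(0, 1)), c("A", "B"), matrix(0.4), k = 2)
  expect_equal(r4$labels, "A")

  expect_error(knn_fit_predict(matrix(c(0, 1)), c("A", "B"), matrix(0.5),
                               k = 3), "parameter error")
})

test_that("k-NN with k = 1 reproduces distinct training data and ignores row order", {
  fx <- two_cluster_fixture()
  self <- knn_fit_predict(fx$X, fx$y, fx$X, k = 1)
  expect_equal(self$labels, fx$y)

  perm <- withr::with_seed(8, sample(nrow(fx$X)))
  test_X <- withr::with_seed(9, matrix(rnorm(20, 5, 3), ncol = 2))
  a <- knn_fit_predict(fx$X, fx$y, test_X, k = 3)
  b <- knn_fit_predict(fx$X[perm, ], fx$y[perm], test_X, k = 3)
  expect_equal(a$labels, b$labels)
  expect_equal(a$scores, b$scores)
})

test_that("k selection picks the smallest k with lowest CV error", {
  fx <- two_cluster_fixture(n_per = 5)
  expect_identical(select_k(fx$X, fx$y, k_max = 4, folds = 5, seed = 1), 1L)
  expect_identical(select_k(fx$X, fx$y, k_max = 1, folds = 5, seed = 1), 1L)
  # identical features: every k ties, the smallest wins
  Xc <- matrix(1, 10, 2)
  expect_identical(select_k(Xc, rep(c("A", "B"), 5), k_max = 3,
                            folds = 5, seed = 1), 1L)
  expect_error(select_k(fx$X, fx$y, k_max = 500, folds = 5, seed = 1),
               "parameter error")
})

test_that("MLR probabilities follow the reference-class logit form", {
  # zero coefficients: uniform probabilities
  m2 <- structure(list(B = matrix(0, 3, 1), labels = c("A", "B"),
                       lambda = 0), class = "mlr_model")
  P2 <- mlr_predict_proba(m2, matrix(rnorm(10), 5, 2))
  expect_equal(unname(P2), matrix(0.5, 5, 2))

  m3 <- structure(list(B = matrix(0, 3, 2), labels = c("A", "B", "C"),
                       lambda = 0), class = "mlr_model")
  P3 <- mlr_predict_proba(m3, matrix(rnorm(10), 5, 2))
  expect_equal(unname(P3), matrix(1 / 3, 5, 3))

  # single attribute with X B = ln 3: P = (3/4, 1/4)
  mln <- structure(list(B = matrix(c(0, log(3)), 2, 1), labels = c("A", "B"),
                        lambda = 0), class = "mlr_model")
  Pln <- mlr_predict_proba(mln, matrix(1))
  expect_equal(unname(Pln[1, ]), c(0.75, 0.25), tolerance = 1e-12)

  expect_error(mlr_predict_proba(m2, matrix(1, 1, 5)), "shape error")
})

test_that("MLR probability rows sum to one for random models", {
  withr::with_seed(12, {
    for (i in 1:50) {
      K <- sample(2:5, 1); p <- sample(1:6, 1); n <- sample(1:20, 1)
      m <- structure(list(B = matrix(rnorm((p + 1) * (K - 1), sd = 2),
                                     p + 1, K - 1),
                          labels = LETTERS[1:K], lambda = 0),
                     class = "mlr_model")
      P <- mlr_predict_proba(m, matrix(rnorm(n * p), n, p))
      expect_equal(rowSums(P), rep(1, n), tolerance = 1e-12)
      expect_true(all(P > 0 & P < 1))
    }
  })
})

test_that("the MLR analytic gradient matches central finite differences", {
  withr::with_seed(21, {
    for (i in 1:5) {
      n <- 25; p <- 3; K <- sample(2:4, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- sample(LETTERS[1:K], n, replace = TRUE)
      while (length(unique(y)) < K) y <- sample(LETTERS[1:K], n, replace = TRUE)
      Y <- outer(y, sort(unique(y)), "==") + 0
      lambda <- 0.1
      b <- rnorm((p + 1) * (K - 1), sd = 0.5)
      ga <- mlr_gradient(b, X, Y, lambda)
      h <- 1e-6
      gn <- vapply(seq_along(b), function(j) {
        bp <- b; bm <- b
        bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
        (mlr_objective(bp, X, Y, lambda) - mlr_objective(bm, X, Y, lambda)) /
          (2 * h)
      }, numeric(1))
      expect_lt(max(abs(ga - gn)) / max(1, max(abs(gn))), 1e-5)
    }
  })
})

test_that("MLR fitting shrinks with heavy ridge and separates separable data", {
  # enormous ridge: coefficients go to zero, probabilities to class priors
  fx <- two_cluster_fixture(n_per = 8)
  big <- mlr_fit(fx$X, fx$y, lambda = 1e12)
  P <- mlr_predict_proba(big, fx$X)
  expect_equal(unname(P), matrix(0.5, nrow(fx$X), 2), tolerance = 1e-4)

  # 1-D perfectly separated classes: training accuracy 1 at tiny ridge
  X1 <- matrix(c(-3, -2.5, -2, 2, 2.5, 3))
  y1 <- rep(c("A", "B"), each = 3)
  fit <- suppressWarnings(mlr_fit(X1, y1, lambda = 1e-8))
  expect_equal(mlr_predict(fit, X1), y1)

  # recorded loss trace is nonincreasing across iterations
  wob <- withr::with_seed(31, {
    X <- matrix(rnorm(80), 40, 2)
    y <- ifelse(X[, 1] + rnorm(40, sd = 0.5) > 0, "A", "B")
    mlr_fit(X, y, lambda = 0.01)
  })
  expect_true(all(diff(wob$loss_trace) <= 1e-8))
  expect_true(wob$converged)
})

test_that("one-vs-one SVM votes across all class pairs", {
  # three tight, far-separated clusters
  centers <- rbind(c(0, 0), c(20, 0), c(0, 20))
  fx <- withr::with_seed(14, {
    X <- do.call(rbind, lapply(1:3, function(i) {
      sweep(matrix(rnorm(20, sd = 0.3), 10, 2), 2, centers[i, ], "+")
    }))
    list(X = X, y = rep(c("A", "B", "C"), each = 10))
  })
  res <- svm_fit_predict(fx$X, fx$y, fx$X, cost = 1, gamma = 0.5)
  expect_equal(res$labels, fx$y)
  # every instance receives K(K-1)/2 = 3 votes in total
  expect_true(all(rowSums(res$votes) == 3))
  # winner's vote share is votes / (K - 1)
  expect_true(all(res$scores >= 0 & res$scores <= 1))
  expect_equal(res$scores[1, "A"], res$votes[1, "A"] / 2)

  # K = 2: single pairwise machine, one vote per instance
  fb <- two_cluster_fixture()
  rb <- svm_fit_predict(fb$X, fb$y, fb$X, cost = 1, gamma = 0.5)
  expect_equal(rb$labels, fb$y)
  expect_true(all(rowSums(rb$votes) == 1))

  expect_error(svm_fit_predict(fb$X, fb$y, fb$X, cost = 0, gamma = 1),
               "domain")
})

test_that("SVM vote aggregation follows the pairwise decision rule", {
  # Plant three collinear clusters so the pairwise decisions are known:
  # AB -> A side, AC -> A side, BC -> C side for a query near A
  fx <- withr::with_seed(15, {
    X <- rbind(matrix(rnorm(10, 0, 0.2), 5, 2),
               matrix(rnorm(10, 10, 0.2), 5, 2),
               matrix(rnorm(10, 5, 0.2), 5, 2))
    list(X = X, y = rep(c("A", "B", "C"), each = 5))
  })
  q <- matrix(c(0.5, 0.5), 1, 2)
  # wide kernel so the query is within reach of every cluster
  res <- svm_fit_predict(fx$X, fx$y, q, cost = 10, gamma = 0.01)
  # A beats B and C near the A cluster; C (midway) beats B
  expect_equal(unname(res$votes[1, ]), c(2L, 0L, 1L))
  expect_equal(res$labels, "A")
})

test_that("classifier predictions are invariant to training row order", {
  fx <- withr::with_seed(16, {
    X <- rbind(matrix(rnorm(30, 0, 1), 15, 2),
               matrix(rnorm(30, 6, 1), 15, 2))
    list(X = X, y = rep(c("A", "B"), each = 15))
  })
  test_X <- withr::with_seed(17, matrix(rnorm(16, 3, 2), 8, 2))
  perm <- withr::with_seed(18, sample(30))

  m1 <- suppressWarnings(mlr_fit(fx$X, fx$y, lambda = 0.01))
  m2 <- suppressWarnings(mlr_fit(fx$X[perm, ], fx$y[perm], lambda = 0.01))
  expect_equal(mlr_predict_proba(m1, test_X), mlr_predict_proba(m2, test_X),
               tolerance = 1e-4)

  s1 <- svm_fit_predict(fx$X, fx$y, test_X, gamma = 0.5)
  s2 <- svm_fit_predict(fx$X[perm, ], fx$y[perm], test_X, gamma = 0.5)
  expect_equal(s1$labels, s2$labels)
})

test_that("min-max normalization fits on training rows and clips test rows", {
  tr <- matrix(c(0, 10, 5, 0, 2, 1), 3, 2)
  nrm <- fit_normalizer(tr, "minmax")
  expect_equal(apply_normalizer(nrm, tr, clip = FALSE)[, 1], c(0, 1, 0.5))
  # out-of-range test values hit the guard range
  te <- matrix(c(-100, 100), 2, 2)
  z <- apply_normalizer(nrm, te)
  expect_equal(z[, 1], c(-0.5, 1.5))
  # constant training feature maps to zero
  cn <- fit_normalizer(matrix(c(1, 1, 5, 7), 2, 2), "minmax")
  expect_equal(apply_normalizer(cn, matrix(c(1, 1, 6, 6), 2, 2))[, 1], c(0, 0))
})
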