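test_that("compute_metrics matches hand-computed values", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$r_squared, 1)
  expect_equal(m$rmse, 0)
  m2 <- compute_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m2$r_squared, 0)   # SS_res == SS_tot == 2
  expect_equal(m2$rmse, sqrt(2 / 3))
})

test_that("metrics are translation invariant and reject constant truth", {
  set.seed(20)
  y <- rnorm(15); p <- y + rnorm(15, 0, 0.2)
  m0 <- compute_metrics(y, p)
  m1 <- compute_metrics(y + 5, p + 5)
  expect_equal(m0$r_squared, m1$r_squared)
  expect_equal(m0$rmse, m1$rmse)
  expect_error(compute_metrics(rep(1, 5), rnorm(5)), "constant")
  expect_error(compute_metrics(1, 1), "length")
})

test_that("noiseless linear data cross-validates perfectly with PLSR", {
  set.seed(21)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- as.numeric(X %*% c(2, -1, 0.5))
  for (folds in c(2, 5, 10)) {
    met <- cross_validate("plsr", X, y, folds,
                          hyper = list(n_components = 3), seed = 1)
    expect_lt(met$rmsecv, 1e-8)
    expect_gt(met$r_squared_cv, 1 - 1e-10)
    expect_equal(met$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("a response independent of X has no cross-validated skill", {
  set.seed(22)
  X <- matrix(rnorm(50 * 5), 50, 5)
  r2 <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    y <- rnorm(50)
    cross_validate("plsr", X, y, folds = 5,
                   hyper = list(n_components = 3), seed = s)$r_squared_cv
  }, numeric(1))
  expect_lte(mean(r2), 0)
})

test_that("cross-validation is reproducible under a fixed seed", {
  set.seed(23)
  X <- matrix(rnorm(45 * 4), 45, 4)
  y <- X[, 1] + rnorm(45, 0, 0.3)
  a <- cross_validate("plsr", X, y, 5, list(n_components = 2), seed = 9)
  b <- cross_validate("plsr", X, y, 5, list(n_components = 2), seed = 9)
  expect_identical(a$rmsecv, b$rmsecv)
  expect_identical(a$cv_predictions, b$cv_predictions)
  c <- cross_validate("plsr", X, y, 5, list(n_components = 2), seed = 10)
  expect_false(identical(a$cv_predictions, c$cv_predictions))
})

test_that("RMSEC is non-increasing in the number of components", {
  set.seed(24)
  n <- 60; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% rnorm(p)) + rnorm(n, 0, 0.5)
  m <- plsr_fit(X, y, 15)
  rmsec <- vapply(seq_len(m$n_components), function(k) {
    compute_metrics(y, plsr_predict(m, X, ncomp = k))$rmse
  }, numeric(1))
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("select_components finds planted dimensionality", {
  set.seed(25)
  n <- 80
  # pure 1-component signal plus tiny noise
  t1 <- rnorm(n)
  X <- outer(t1, rnorm(20)) + matrix(rnorm(n * 20, 0, 1e-3), n)
  y <- 2 * t1 + rnorm(n, 0, 1e-3)
  expect_equal(as.integer(select_components(X, y, 8, folds = 5, seed = 1)), 1L)

  # max_components = 1 trivially returns 1
  expect_equal(as.integer(select_components(X, y, 1, folds = 5, seed = 1)), 1L)

  # three orthogonal planted components of comparable strength
  hits <- vapply(1:10, function(s) {
    set.seed(300 + s)
    scores <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n)
    X3 <- scores %*% matrix(rnorm(3 * 25), 3, 25) +
      matrix(rnorm(n * 25, 0, 0.05), n)
    y3 <- as.numeric(scores %*% c(1, 0.8, 1.2)) + rnorm(n, 0, 0.05)
    as.integer(select_components(X3, y3, 8, folds = 5, seed = s))
  }, integer(1))
  expect_true(all(hits >= 2 & hits <= 4))
})

test_that("fold construction validates its arguments", {
  X <- matrix(rnorm(20), 10, 2); y <- rnorm(10)
  expect_error(cross_validate("plsr", X, y, folds = 1), "folds")
  expect_error(cross_validate("plsr", X, y, folds = 11), "fewer samples")
  expect_error(cross_validate("plsr", X, y, folds = 6,
                              hyper = list(n_components = 1)),
               "fewer than 2")
})
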