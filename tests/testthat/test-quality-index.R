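test_that("min-max normalization maps bounds to the unit interval", {
  up <- attribute_spec("x", "quality_increasing")
  down <- attribute_spec("x", "quality_decreasing")
  b <- normalization_bounds("x", 0, 10)
  expect_equal(normalize_attribute(5, b, up), 0.5)
  expect_equal(normalize_attribute(10, b, down), 0)
  expect_equal(normalize_attribute(c(0, 10), b, up), c(0, 1))
  expect_equal(normalize_attribute(c(0, 10), b, down), c(1, 0))

  # hardness endpoints under CA storage, bounds from its own extremes
  hb <- normalization_bounds("hardness", 73.59, 99.81)
  hs <- attribute_spec("hardness", "quality_increasing", "N")
  expect_equal(normalize_attribute(c(99.81, 73.59), hb, hs), c(1, 0))
})

test_that("out-of-bound values are clipped with a warning; degenerate bounds rejected", {
  up <- attribute_spec("x", "quality_increasing")
  b <- normalization_bounds("x", 0, 10)
  expect_warning(v <- normalize_attribute(c(-2, 5, 14), b, up), "clipped")
  expect_equal(v, c(0, 0.5, 1))
  expect_error(normalization_bounds("x", 3, 3), "x_max > x_min")
})

test_that("compute_qi averages attributes per sample", {
  expect_equal(compute_qi(replicate(10, 1, simplify = FALSE))$qi, 1)
  expect_equal(compute_qi(list(a = 0.2, b = 0.6))$qi, 0.4)
  ten <- as.list(setNames(seq(0.1, 1, by = 0.1), paste0("a", 1:10)))
  expect_equal(compute_qi(ten)$qi, 0.55)
  expect_equal(compute_qi(ten)$n_attributes, 10L)
})

test_that("compute_qi rejects ragged, empty and out-of-range input", {
  expect_error(compute_qi(list(a = c(0.1, 0.2), b = 0.3)), "unequal")
  expect_error(compute_qi(list()), "non-empty")
  expect_error(compute_qi(list(a = 1.2)), "\\[0, 1\\]")
})

test_that("qi stays in [0, 1] and is invariant to attribute order", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    n <- sample(3:30, 1)
    vals <- replicate(k, runif(n), simplify = FALSE)
    names(vals) <- paste0("attr", seq_len(k))
    qi1 <- compute_qi(vals)$qi
    expect_true(all(qi1 >= 0 & qi1 <= 1))
    qi2 <- compute_qi(rev(vals))$qi
    expect_equal(qi1, qi2)
  }
})

test_that("noiseless exponential series is recovered to 6+ significant digits", {
  days <- seq(0, 120, by = 20)
  set.seed(5)
  for (i in 1:5) {
    A <- runif(1, 0.3, 1.5); k <- runif(1, 0.002, 0.05)
    m <- fit_shelf_life(days, A * exp(-k * days))
    expect_equal(m$amplitude, A, tolerance = 1e-7)
    expect_equal(m$decay_rate, k, tolerance = 1e-7)
    expect_gte(m$r_squared, 1 - 1e-10)
  }
})

test_that("a flat series yields the degenerate fit k = 0, A = mean", {
  m <- fit_shelf_life(c(0, 30, 60, 90), rep(0.62, 4))
  expect_equal(m$decay_rate, 0, tolerance = 1e-10)
  expect_equal(m$amplitude, 0.62, tolerance = 1e-10)
})

test_that("parameters are recovered from noisy series within Monte-Carlo tolerance", {
  days <- rep(seq(0, 120, by = 20), each = 100)
  set.seed(42)
  qi <- 0.87 * exp(-0.01 * days) + rnorm(length(days), 0, 0.02)
  m <- fit_shelf_life(days, qi)
  expect_lt(abs(m$amplitude - 0.87), 0.03)
  expect_lt(abs(m$decay_rate - 0.01), 0.002)
})

test_that("fit_shelf_life validates its input", {
  expect_error(fit_shelf_life(c(0, 0, 20, 20), c(1, 1, 0.8, 0.8)),
               "3 distinct day")
  expect_error(fit_shelf_life(c(-1, 10, 20), c(1, 0.9, 0.8)), "non-negative")
})

test_that("predict_qi evaluates the decay curve and rejects negative days", {
  m <- shelf_life_model(0.87, 0.01)
  expect_equal(predict_qi(m, 0), 0.87)
  expect_equal(predict_qi(m, 100), 0.87 * exp(-1), tolerance = 1e-12)
  expect_equal(predict_qi(shelf_life_model(0.5, 0), c(0, 40, 999)),
               rep(0.5, 3))
  expect_error(predict_qi(m, -1), "non-negative")
  # strictly decreasing in day for positive decay rate
  d <- sort(runif(20, 0, 200))
  expect_true(all(diff(predict_qi(m, d)) < 0))
})

test_that("shelf-life model and bounds round-trip through JSON", {
  m <- fit_shelf_life(seq(0, 120, 20), 0.87 * exp(-0.01 * seq(0, 120, 20)))
  b <- list(hardness = normalization_bounds("hardness", 73.59, 99.81))
  path <- withr::local_tempfile(fileext = ".json")
  write_shelf_life_model(m, path, bounds = b)
  back <- read_shelf_life_model(path)
  expect_equal(back$model$amplitude, m$amplitude)
  expect_equal(back$model$decay_rate, m$decay_rate)
  expect_equal(back$bounds[[1]]$x_min, 73.59)
  expect_equal(back$bounds[[1]]$x_max, 99.81)
})
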