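test_that("validate_grid accepts the instrument grid and rejects bad input", {
  g <- validate_grid(seq(285, 1200, by = 3))
  expect_equal(g$n_points, 306L)
  expect_equal(g$stop_nm, 1200)
  expect_equal(g$step_nm, 3)
  expect_error(validate_grid(c(285, 288, 292)), "not uniform")
  expect_error(validate_grid(285), "at least two")
  expect_error(validate_grid(c(288, 285, 291)), "strictly increasing")
})

test_that("spectrum constructor enforces kind-specific invariants", {
  g <- wavelength_grid(285, 3, 5)
  expect_error(new_spectrum(c(1, 2, 3), g), "length")
  expect_error(new_spectrum(c(0, 10, 101, 50, 20), g), "\\[0, 100\\]")
  expect_error(new_spectrum(c(0, 10, NA, 50, 20), g), "non-finite")
  # absorbance spectra are unconstrained in sign
  s <- new_spectrum(c(-1, 0, 2, 1, 0.5), g, kind = "absorbance")
  expect_s3_class(s, "spectrum")
})

test_that("average_scans is the pointwise mean and checks compatibility", {
  s <- small_spectrum(c(10, 20, 30, 40))
  expect_equal(average_scans(list(s, s, s))$values, s$values)
  s2 <- small_spectrum(c(30, 40, 50, 60))
  expect_equal(average_scans(list(s, s2))$values, c(20, 30, 40, 50))
  other_grid <- new_spectrum(c(1, 2, 3, 4), wavelength_grid(400, 2, 4),
                             "reflectance_percent", "s1")
  expect_error(average_scans(list(s, other_grid)), "differ")
  expect_error(average_scans(list()), "non-empty")
})

test_that("averaging replicate noisy scans concentrates around the truth", {
  set.seed(9)
  g <- wavelength_grid()
  truth <- 50 + 20 * sin(grid_wavelengths(g) / 100)
  sigma <- 1.5
  scans <- lapply(1:3, function(i) {
    new_spectrum(truth + rnorm(g$n_points, 0, sigma), g,
                 "reflectance_percent", "f1")
  })
  avg <- average_scans(scans)
  frac_close <- mean(abs(avg$values - truth) <= 3 * sigma / sqrt(3))
  expect_gte(frac_close, 0.99)
})

test_that("absorbance conversion follows A = log10(100 / R%)", {
  expect_equal(to_absorbance(small_spectrum(rep(100, 4)))$values, rep(0, 4))
  expect_equal(to_absorbance(small_spectrum(c(10, 100, 100, 100)))$values[1], 1)
  expect_equal(to_absorbance(small_spectrum(rep(50, 4)))$values,
               rep(log10(2), 4))
  err <- tryCatch(to_absorbance(small_spectrum(c(0, 50, 50, 50))),
                  error = identity)
  expect_match(conditionMessage(err), "285") # names the offending wavelength
})

test_that("SG second derivative annihilates lines and is exact on quadratics", {
  g <- wavelength_grid()
  wl <- grid_wavelengths(g)
  const <- new_spectrum(rep(5, g$n_points), g, "absorbance")
  expect_equal(sg_second_derivative(const)$values, rep(0, g$n_points),
               tolerance = 1e-12)
  line <- new_spectrum(0.01 * wl + 2, g, "absorbance")
  expect_equal(max(abs(sg_second_derivative(line)$values)), 0,
               tolerance = 1e-10)
  quad <- new_spectrum(wl^2, g, "absorbance")
  d2 <- sg_second_derivative(quad, window_points = 15, poly_order = 3)
  expect_equal(d2$values, rep(2, g$n_points), tolerance = 1e-8)
  expect_identical(d2$kind, "second_derivative")
})

test_that("SG second derivative matches the brute-force windowed polyfit oracle", {
  g <- wavelength_grid(400, 2, 80)
  wl <- grid_wavelengths(g)
  set.seed(14)
  # random cubic plus noise: oracle must agree everywhere, edges included
  vals <- 3 - 0.02 * wl + 1e-5 * wl^2 - 2e-9 * wl^3 + rnorm(80, 0, 0.05)
  s <- new_spectrum(vals, g, "absorbance")
  got <- sg_second_derivative(s, window_points = 15, poly_order = 3)$values
  want <- sg_oracle(vals, wl, window = 15, order = 3)
  expect_equal(got, want, tolerance = 1e-8)

  # a second configuration: wider window, quartic polynomial
  got2 <- sg_second_derivative(s, window_points = 21, poly_order = 4)$values
  want2 <- sg_oracle(vals, wl, window = 21, order = 4)
  expect_equal(got2, want2, tolerance = 1e-8)
})

test_that("SG second derivative is linear in its input", {
  g <- wavelength_grid(500, 3, 60)
  set.seed(15)
  f <- rnorm(60); h <- rnorm(60)
  a <- 1.7; b <- -0.6
  d2 <- function(v) sg_second_derivative(
    new_spectrum(v, g, "absorbance"))$values
  expect_equal(d2(a * f + b * h), a * d2(f) + b * d2(h), tolerance = 1e-10)
})

test_that("derivative scaling is per physical nm^2, independent of the grid step", {
  # same quadratic in wavelength sampled on two different steps
  for (step in c(1, 3, 10)) {
    g <- wavelength_grid(400, step, 40)
    wl <- grid_wavelengths(g)
    d2 <- sg_second_derivative(new_spectrum(0.5 * wl^2, g, "absorbance"))
    expect_equal(d2$values, rep(1, 40), tolerance = 1e-8)
  }
})

test_that("SG argument validation", {
  s <- small_spectrum(runif(20, 1, 99))
  expect_error(sg_second_derivative(s, window_points = 14), "odd")
  expect_error(sg_second_derivative(s, poly_order = 1), "poly_order")
  expect_error(sg_second_derivative(s, window_points = 21), "exceeds")
})

test_that("spectra CSV dialect round-trips values, grid and metadata", {
  g <- wavelength_grid(285, 3, 10)
  vals <- matrix(runif(30, 1, 99), 3, 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(path, vals, g, sample_id = c("a", "a", "b"),
                    scan_no = c(1, 2, 1))
  back <- read_spectra_csv(path)
  expect_equal(back$values, vals, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$grid$n_points, 10L)
  expect_equal(back$data$sample_id, c("a", "a", "b"))
})
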