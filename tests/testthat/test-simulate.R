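test_that("noiseless trajectories hit the configured endpoints exactly", {
  cfg <- small_cfg(noise_scale = 0)
  attrs <- simulate_attributes(1, cfg)
  ca0 <- attrs[attrs$condition == "ca" & attrs$day == 0, ]
  expect_equal(ca0$hardness, 99.81)
  expect_equal(ca0$tss, 20.31)
  expect_equal(ca0$mc, 70.99)
  expect_equal(ca0$delta_e, 0)
  expect_equal(ca0$bi, 83.31)
  ca120 <- attrs[attrs$condition == "ca" & attrs$day == 120, ]
  expect_equal(ca120$hardness, 73.59)
  expect_equal(ca120$tss, 24.12)
  expect_equal(ca120$mc, 62.64)
  amb20 <- attrs[attrs$condition == "ambient" & attrs$day == 20, ]
  expect_equal(amb20$hardness, 52.29)
  expect_equal(amb20$s_overall, 3.70)
})

test_that("deterioration parity: all conditions end at the same latent state", {
  cfg <- small_cfg()
  ends <- vapply(names(cfg$conditions), function(cond) {
    dateqi:::latent_quality(cfg, cond, cfg$conditions[[cond]]$shelf_days)
  }, numeric(1))
  expect_equal(unname(ends), rep(exp(-1.2), 3), tolerance = 1e-12)
  expect_equal(cfg$conditions$ca$decay_rate, 0.01)
})

test_that("the same seed reproduces the identical cohort", {
  a <- simulate_cohort(3, small_cfg(seed = 31))
  b <- simulate_cohort(3, small_cfg(seed = 31))
  expect_identical(a$attributes, b$attributes)
  expect_identical(a$scans, b$scans)
  c <- simulate_cohort(3, small_cfg(seed = 32))
  expect_false(identical(a$scans, c$scans))
})

test_that("noiseless Q_i under CA storage decreases monotonically in day", {
  cfg <- small_cfg(noise_scale = 0)
  attrs <- simulate_attributes(1, cfg)
  bounds <- estimate_bounds(attrs)
  qi <- cohort_quality_index(attrs, bounds)
  ca <- qi[qi$condition == "ca", ]
  ca <- ca[order(ca$day), ]
  expect_true(all(diff(ca$qi) < 0))
  expect_true(all(qi$qi >= 0 & qi$qi <= 1))
})

test_that("cell means converge to the configured trajectory (n = 500)", {
  cfg <- small_cfg(seed = 77)
  attrs <- simulate_attributes(500, cfg)
  cell <- attrs[attrs$condition == "cold" & attrs$day == 40, ]
  for (nm in c("tss", "hardness", "mc", "bi")) {
    a <- cfg$attributes[[nm]]
    se <- a$sd / sqrt(nrow(cell))
    expect_lt(abs(mean(cell[[nm]]) - a$end[["cold"]]), 3 * se)
  }
})

test_that("sensory scores respect the 9-point hedonic scale under heavy noise", {
  cfg <- small_cfg(seed = 5, noise_scale = 6)
  attrs <- simulate_attributes(50, cfg)
  for (nm in c("s_texture", "s_taste", "s_color", "s_overall")) {
    expect_true(all(attrs[[nm]] >= 1 & attrs[[nm]] <= 9))
  }
  expect_true(all(attrs$delta_e >= 0))
})

test_that("simulated spectra are valid and chlorophyll-dominated in their quality response", {
  cfg <- small_cfg(noise_scale = 0)
  fresh <- list(condition = "ca", day = 0, maturity = 90, sample_id = "f")
  aged <- list(condition = "ca", day = 120, maturity = 90, sample_id = "a")
  s_fresh <- simulate_spectrum(fresh, cfg)
  s_aged <- simulate_spectrum(aged, cfg)
  expect_s3_class(s_fresh, "spectrum")
  expect_true(all(s_fresh$values > 0 & s_fresh$values <= 100))

  wl <- grid_wavelengths(cfg$grid)
  dA <- abs(to_absorbance(s_fresh)$values - to_absorbance(s_aged)$values)
  expect_lte(abs(wl[which.max(dA)] - 672), 30)

  # identical states give identical spectra when noise is off
  expect_identical(simulate_spectrum(fresh, cfg)$values, s_fresh$values)
})

test_that("make_dataset produces the 75/25 stratified split", {
  ds <- make_dataset(1000, small_cfg(seed = 42))
  expect_equal(nrow(ds$train$attributes), 750)
  expect_equal(nrow(ds$test$attributes), 250)
  # scans follow their fruit
  expect_equal(nrow(ds$train$scans), 750 * 3)
  # stratification: every (condition, day) cell is represented in both parts
  tr <- table(ds$train$attributes$condition, ds$train$attributes$day)
  te <- table(ds$test$attributes$condition, ds$test$attributes$day)
  expect_true(all(te[tr > 0] > 0))

  # 8 fruits cannot fill 12 cells with 2+ each: falls back to unstratified
  expect_warning(ds8 <- make_dataset(8, small_cfg(seed = 1)), "unstratified")
  expect_equal(nrow(ds8$train$attributes), 6)
  expect_equal(nrow(ds8$test$attributes), 2)

  ds_a <- make_dataset(60, small_cfg(seed = 9))
  ds_b <- make_dataset(60, small_cfg(seed = 9))
  expect_identical(ds_a$train$attributes$sample_id,
                   ds_b$train$attributes$sample_id)
})

test_that("PLSR from second-derivative spectra recovers moisture content", {
  # planted-signal recoverability: the water bands carry MC
  cohort <- simulate_cohort(25, small_cfg(seed = 42))  # 300 fruits
  prep <- preprocess_cohort(cohort)
  met <- cross_validate("plsr", prep$X, cohort$attributes$mc, folds = 5,
                        hyper = list(n_components = 12), seed = 42)
  expect_gt(met$r_squared_cv, 0.85)
})

test_that("write_cohort emits the CSV dialects plus a manifest", {
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(2, small_cfg(seed = 3))
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "attributes.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 3)
  back <- read_cohort_csv(file.path(dir, "spectra.csv"),
                          file.path(dir, "attributes.csv"))
  expect_equal(back$grid$n_points, cohort$grid$n_points)
  expect_equal(dim(back$scans), dim(cohort$scans))
  expect_equal(back$scans, cohort$scans, ignore_attr = TRUE, tolerance = 1e-10)
})
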