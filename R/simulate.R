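#' Default storage-trajectory configuration for a Barhi-date cohort
#'
#' Encodes the study design the generator emulates: three maturity stages
#' (80/90/100% yellowish), three storage regimes with shelf lives of 20
#' (ambient, 25 degC), 40 (cold, 1 degC) and 120 days (controlled
#' atmosphere), fruit sampled every 20 days up to each regime's shelf life,
#' and per-attribute start/end values taken from the measured storage
#' trajectories: TSS rises from 20.31% (to 24.12 / 23.39 / 25.03% under
#' CA / cold / ambient), colour difference from 0 (to 11.68 / 11.28 /
#' 12.16), browning index from 83.31 (to 89.45 / 91.45 / 89.76), while
#' hardness falls from 99.81 N (to 73.59 / 76.85 / 52.29 N), moisture from
#' 70.99% (to 62.64 / 62.58 / 60.91%) and the four 9-point hedonic scores
#' from 8.4/8.7/8.9/8.5 to roughly 3-4.
#'
#' A latent quality state decays exponentially at 0.01 per day under CA;
#' ambient and cold rates are set so the latent state at each regime's
#' terminal day equals the CA value at 120 days (deterioration parity at
#' end of shelf life). Every attribute is an affine function of the latent
#' state between its endpoints plus Gaussian noise at the scale of the
#' reported standard deviations.
#'
#' Spectra are built from Gaussian absorption bands on the 285-1200 nm
#' grid: a chlorophyll band at 672 nm whose amplitude tracks the latent
#' state, water bands at 760 and 970 nm tracking moisture, and a broad
#' sugar-linked band at 910 nm tracking TSS, on a smooth baseline with
#' additive (0.3% reflectance RMS) plus multiplicative (1%) noise.
#'
#' @param seed integer seed for all generator randomness.
#' @param noise_scale multiplier applied to every noise SD (0 gives
#'   noiseless trajectories and spectra).
#' @return A `trajectory_config` list; all fields may be modified before
#'   passing to the simulators.
#' @export
trajectory_config <- function(seed = 42L, noise_scale = 1) {
  k_ca <- 0.01
  latent_end <- exp(-k_ca * 120)   # latent state at end of shelf life
  conditions <- list(
    ambient = list(shelf_days = 20,  decay_rate = -log(latent_end) / 20),
    cold    = list(shelf_days = 40,  decay_rate = -log(latent_end) / 40),
    ca      = list(shelf_days = 120, decay_rate = k_ca)
  )
  ends <- function(ca, cold, ambient) c(ca = ca, cold = cold, ambient = ambient)
  attributes <- list(
    tss       = list(start = 20.31, end = ends(24.12, 23.39, 25.03),
                     sd = 1.00, direction = "quality_decreasing", units = "%"),
    delta_e   = list(start = 0,     end = ends(11.68, 11.28, 12.16),
                     sd = 0.40, direction = "quality_decreasing", units = ""),
    bi        = list(start = 83.31, end = ends(89.45, 91.45, 89.76),
                     sd = 0.60, direction = "quality_decreasing", units = ""),
    hardness  = list(start = 99.81, end = ends(73.59, 76.85, 52.29),
                     sd = 0.80, direction = "quality_increasing", units = "N"),
    mc        = list(start = 70.99, end = ends(62.64, 62.58, 60.91),
                     sd = 0.60, direction = "quality_increasing", units = "%"),
    s_texture = list(start = 8.4, end = ends(3.13, 3.06, 3.20),
                     sd = 0.70, direction = "quality_increasing", units = "hedonic"),
    s_taste   = list(start = 8.7, end = ends(3.80, 4.05, 3.89),
                     sd = 0.70, direction = "quality_increasing", units = "hedonic"),
    s_color   = list(start = 8.9, end = ends(3.30, 3.45, 3.52),
                     sd = 0.70, direction = "quality_increasing", units = "hedonic"),
    s_overall = list(start = 8.5, end = ends(3.84, 3.83, 3.70),
                     sd = 0.70, direction = "quality_increasing", units = "hedonic")
  )
  bands <- list(
    chlorophyll = list(center = 672, width = 18, amplitude = 0.50,
                       link = "latent"),
    water_a     = list(center = 760, width = 25, amplitude = 0.12,
                       link = "mc"),
    water_b     = list(center = 970, width = 35, amplitude = 0.25,
                       link = "mc"),
    sugar       = list(center = 910, width = 30, amplitude = 0.10,
                       link = "tss")
  )
  structure(list(
    seed = as.integer(seed),
    noise_scale = noise_scale,
    day_step = 20,
    maturities = c(80, 90, 100),
    conditions = conditions,
    attributes = attributes,
    bands = bands,
    baseline = list(level = 0.25, slope = 0.10),
    spectra_noise = list(additive_sd = 0.3, multiplicative_sd = 0.01),
    grid = wavelength_grid(),
    n_scans = 3L,
    sensory_range = c(1, 9)
  ), class = "trajectory_config")
}

#' @export
print.trajectory_config <- function(x, ...) {
  cat("Fruit-cohort trajectory configuration\n")
  cat("  seed:", x$seed, " noise_scale:", x$noise_scale, "\n")
  cat("  conditions:",
      paste(sprintf("%s (%d d, k = %.4f/d)", names(x$conditions),
                    vapply(x$conditions, `[[`, numeric(1), "shelf_days"),
                    vapply(x$conditions, `[[`, numeric(1), "decay_rate")),
            collapse = ", "), "\n")
  cat("  attributes:", paste(names(x$attributes), collapse = ", "), "\n")
  invisible(x)
}

condition_days <- function(cfg, condition) {
  seq(0, cfg$conditions[[condition]]$shelf_days, by = cfg$day_step)
}

latent_quality <- function(cfg, condition, day) {
  exp(-cfg$conditions[[condition]]$decay_rate * day)
}

# noiseless attribute value as an affine function of the latent state:
# latent 1 (day 0) -> start, latent at shelf-life end -> condition endpoint
attribute_mean <- function(cfg, name, condition, latent) {
  a <- cfg$attributes[[name]]
  l_end <- exp(-0.01 * 120)
  frac <- (latent - l_end) / (1 - l_end)
  a$end[[condition]] + (a$start - a$end[[condition]]) * frac
}

design_cells <- function(cfg) {
  cells <- do.call(rbind, lapply(names(cfg$conditions), function(cond) {
    data.frame(condition = cond, day = condition_days(cfg, cond),
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  cells
}

#' Simulate per-fruit quality attributes
#'
#' Generates `n_per_cell` fruits for every (condition, day) cell of the
#' design, with attributes drawn around their latent-state trajectory (see
#' [trajectory_config()]) with Gaussian noise. Sensory scores are clipped
#' to the 1-9 hedonic scale and the colour difference to >= 0. Maturity
#' stages are assigned cyclically within each cell.
#'
#' @param n_per_cell fruits per (condition, day) cell (>= 1).
#' @param cfg a [trajectory_config()].
#' @return Data frame with columns `sample_id`, `maturity`, `condition`,
#'   `day`, `latent_quality` and one column per configured attribute.
#' @examples
#' head(simulate_attributes(2, trajectory_config(seed = 1)))
#' @export
simulate_attributes <- function(n_per_cell, cfg = trajectory_config()) {
  stopifnot(n_per_cell >= 1)
  cells <- design_cells(cfg)
  counts <- rep.int(n_per_cell, nrow(cells))
  simulate_attributes_counts(counts, cfg)
}

# core generator: one row per fruit, cell sizes given explicitly
simulate_attributes_counts <- function(counts, cfg) {
  cells <- design_cells(cfg)
  stopifnot(length(counts) == nrow(cells))
  idx <- rep(seq_len(nrow(cells)), counts)
  n <- length(idx)
  condition <- cells$condition[idx]
  day <- cells$day[idx]
  latent <- exp(-vapply(cfg$conditions[condition], `[[`, numeric(1),
                        "decay_rate") * day)
  maturity <- cfg$maturities[(sequence(counts) - 1L) %% length(cfg$maturities) + 1L]
  out <- data.frame(
    sample_id = sprintf("F%04d", seq_len(n)),
    maturity = maturity, condition = condition, day = day,
    latent_quality = latent, stringsAsFactors = FALSE)
  for (name in names(cfg$attributes)) {
    a <- cfg$attributes[[name]]
    mu <- mapply(function(cond, lat) attribute_mean(cfg, name, cond, lat),
                 condition, latent, USE.NAMES = FALSE)
    if (a$start == a$end[[1]] && length(unique(a$end)) == 1L) {
      warning("simulate_attributes: attribute '", name,
              "' has identical endpoints; it is pure noise", call. = FALSE)
    }
    vals <- mu + stats::rnorm(n, 0, a$sd * cfg$noise_scale)
    if (startsWith(name, "s_")) {
      vals <- pmin(pmax(vals, cfg$sensory_range[1]), cfg$sensory_range[2])
    }
    if (name == "delta_e") vals <- pmax(vals, 0)
    out[[name]] <- vals
  }
  out
}

#' Simulate one reflectance spectrum for a fruit state
#'
#' Builds absorbance as a smooth baseline plus the configured Gaussian
#' bands (amplitudes linked to the latent state, moisture and TSS of the
#' fruit), converts to percent reflectance as `100 * 10^(-A)`, and adds
#' heteroscedastic noise (multiplicative plus additive). Values are clipped
#' into (0, 100].
#'
#' @param state one-row data frame (or list) with `condition`, `day`,
#'   `maturity`, `sample_id` fields, as produced by [simulate_attributes()].
#' @param cfg a [trajectory_config()].
#' @return A [new_spectrum()] of kind `"reflectance_percent"`.
#' @export
simulate_spectrum <- function(state, cfg = trajectory_config()) {
  vals <- spectrum_matrix(data.frame(condition = state$condition,
                                     day = state$day,
                                     maturity = state$maturity,
                                     stringsAsFactors = FALSE), cfg)
  new_spectrum(vals[1, ], cfg$grid, "reflectance_percent",
               state$sample_id %||% "sample")
}

# vectorized band model: one spectrum row per state row (adds noise)
spectrum_matrix <- function(states, cfg) {
  wl <- grid_wavelengths(cfg$grid)
  n <- nrow(states)
  latent <- exp(-vapply(cfg$conditions[states$condition], `[[`, numeric(1),
                        "decay_rate") * states$day)
  mc0 <- mapply(function(cond, lat) attribute_mean(cfg, "mc", cond, lat),
                states$condition, latent, USE.NAMES = FALSE)
  tss0 <- mapply(function(cond, lat) attribute_mean(cfg, "tss", cond, lat),
                 states$condition, latent, USE.NAMES = FALSE)
  links <- list(latent = latent,
                mc = mc0 / cfg$attributes$mc$start,
                tss = tss0 / cfg$attributes$tss$start)
  baseline <- cfg$baseline$level +
    cfg$baseline$slope * (wl - cfg$grid$start_nm) /
      (cfg$grid$stop_nm - cfg$grid$start_nm)
  A <- matrix(baseline, n, cfg$grid$n_points, byrow = TRUE)
  for (b in cfg$bands) {
    shape <- exp(-0.5 * ((wl - b$center) / b$width)^2)
    A <- A + (b$amplitude * links[[b$link]]) %o% shape
  }
  R <- 100 * 10^(-A)
  if (cfg$noise_scale > 0) {
    ns <- cfg$spectra_noise
    R <- R * (1 + matrix(stats::rnorm(length(R), 0,
                                      ns$multiplicative_sd * cfg$noise_scale),
                         n)) +
      matrix(stats::rnorm(length(R), 0, ns$additive_sd * cfg$noise_scale), n)
  }
  pmin(pmax(R, 1e-4), 100)
}

#' Simulate a full fruit cohort (attributes plus replicate spectra scans)
#'
#' Seeds the RNG from `cfg$seed`, draws attributes for every design cell
#' and `cfg$n_scans` reflectance scans per fruit. The same configuration
#' and seed always reproduce the identical cohort.
#'
#' @param n_per_cell fruits per (condition, day) cell.
#' @param cfg a [trajectory_config()].
#' @return A `fruit_cohort`: list with `attributes` (data frame), `scans`
#'   (matrix, `n_scans` rows per fruit), `scan_info` (sample_id/scan_no),
#'   `grid` and `cfg`.
#' @export
simulate_cohort <- function(n_per_cell, cfg = trajectory_config()) {
  cells <- design_cells(cfg)
  simulate_cohort_counts(rep.int(n_per_cell, nrow(cells)), cfg)
}

simulate_cohort_counts <- function(counts, cfg) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(cfg$seed)
  attrs <- simulate_attributes_counts(counts, cfg)
  per_scan <- attrs[rep(seq_len(nrow(attrs)), each = cfg$n_scans),
                    c("sample_id", "condition", "day", "maturity")]
  per_scan$scan_no <- rep_len(seq_len(cfg$n_scans), nrow(per_scan))
  scans <- spectrum_matrix(per_scan, cfg)
  rownames(scans) <- NULL
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  structure(list(attributes = attrs,
                 scans = scans,
                 scan_info = data.frame(sample_id = per_scan$sample_id,
                                        scan_no = per_scan$scan_no,
                                        stringsAsFactors = FALSE),
                 grid = cfg$grid,
                 cfg = cfg),
            class = "fruit_cohort")
}

#' @export
print.fruit_cohort <- function(x, ...) {
  cat(sprintf("<fruit_cohort> %d fruits, %d scans, %d-point grid\n",
              nrow(x$attributes), nrow(x$scans), x$grid$n_points))
  invisible(x)
}

subset_cohort <- function(cohort, keep) {
  ids <- cohort$attributes$sample_id[keep]
  scan_keep <- cohort$scan_info$sample_id %in% ids
  structure(list(attributes = cohort$attributes[keep, , drop = FALSE],
                 scans = cohort$scans[scan_keep, , drop = FALSE],
                 scan_info = cohort$scan_info[scan_keep, , drop = FALSE],
                 grid = cohort$grid, cfg = cohort$cfg),
            class = "fruit_cohort")
}

#' Generate a cohort and split it into training and test sets
#'
#' Generates `n_total` fruits spread as evenly as possible over the
#' (condition, day) design cells, then performs a seeded 75/25 split
#' stratified by condition and day: the training set holds
#' `floor(0.75 * n_total)` fruits and the test set the remainder. Strata
#' with fewer than 2 fruits trigger a fallback to an unstratified split
#' (with a warning).
#'
#' @param n_total total number of fruits (>= 8).
#' @param cfg a [trajectory_config()]; its seed drives both the simulation
#'   and the split.
#' @return List with `fruit_cohort` elements `train` and `test`.
#' @examples
#' ds <- make_dataset(40, trajectory_config(seed = 7))
#' nrow(ds$train$attributes) # 30
#' @export
make_dataset <- function(n_total, cfg = trajectory_config()) {
  if (n_total < 8) stop("make_dataset: need n_total >= 8", call. = FALSE)
  cells <- design_cells(cfg)
  ncell <- nrow(cells)
  counts <- rep.int(n_total %/% ncell, ncell)
  extra <- n_total %% ncell
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  cohort <- simulate_cohort_counts(counts, cfg)

  n_train_target <- floor(0.75 * n_total)
  attrs <- cohort$attributes
  stratum <- interaction(attrs$condition, attrs$day, drop = TRUE)

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(cfg$seed + 1L)
  if (any(table(stratum) < 2L)) {
    warning("make_dataset: stratum with < 2 fruits; falling back to an ",
            "unstratified split", call. = FALSE)
    train_idx <- sample.int(n_total, n_train_target)
  } else {
    strata <- split(seq_len(n_total), stratum)
    base <- vapply(strata, function(s) floor(0.75 * length(s)), numeric(1))
    frac <- vapply(strata, function(s) 0.75 * length(s), numeric(1)) - base
    deficit <- n_train_target - sum(base)
    if (deficit > 0) {
      bump <- order(frac, decreasing = TRUE)[seq_len(deficit)]
      base[bump] <- base[bump] + 1
    }
    train_idx <- unlist(mapply(function(s, k) sample(s, k), strata, base,
                               SIMPLIFY = FALSE), use.names = FALSE)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  keep_train <- seq_len(n_total) %in% train_idx
  list(train = subset_cohort(cohort, keep_train),
       test = subset_cohort(cohort, !keep_train))
}

#' Write a cohort to CSV files (plus a manifest)
#'
#' Emits the attribute table and the wide spectra table in the package's
#' CSV dialects, together with a `manifest.json` recording the seed and a
#' hash of the configuration.
#'
#' @param cohort a `fruit_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$attributes, file.path(dir, "attributes.csv"),
                   row.names = FALSE)
  write_spectra_csv(file.path(dir, "spectra.csv"), cohort$scans, cohort$grid,
                    sample_id = cohort$scan_info$sample_id,
                    scan_no = cohort$scan_info$scan_no)
  manifest <- list(seed = cohort$cfg$seed,
                   n_fruits = nrow(cohort$attributes),
                   config_hash = config_hash(cohort$cfg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

config_hash <- function(cfg) {
  raw <- serialize(cfg, NULL, version = 2)
  # tiny rolling hash; enough to detect config drift in a manifest
  sprintf("%08x",
          sum(as.numeric(raw) * (seq_along(raw) %% 97 + 1)) %% 2^31)
}
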