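# End-to-end orchestration: simulate/load -> preprocess -> Q_i ->
# calibrate -> report. Each stage is also exported on its own so tests and
# interactive work can target it directly.

QI_DEFAULT_ATTRIBUTES <- c("tss", "delta_e", "bi", "hardness", "mc",
                           "s_texture", "s_taste", "s_color", "s_overall")
QI_DEFAULT_DIRECTIONS <- c(
  tss = "quality_decreasing", delta_e = "quality_decreasing",
  bi = "quality_decreasing", hardness = "quality_increasing",
  mc = "quality_increasing", s_texture = "quality_increasing",
  s_taste = "quality_increasing", s_color = "quality_increasing",
  s_overall = "quality_increasing")

#' Validated run configuration
#'
#' Assembles and validates the configuration for [run_calibration()].
#' Unknown keys are rejected so typos fail loudly before any stage runs.
#'
#' @param seed integer; the single seed that determines every stochastic
#'   choice downstream (simulation noise, split, fold shuffles, ANN
#'   initialization).
#' @param simulate if `TRUE`, generate the cohort; otherwise
#'   `spectra_csv`/`attributes_csv` must point to input files.
#' @param n_total cohort size when simulating.
#' @param noise_scale generator noise multiplier when simulating.
#' @param spectra_csv,attributes_csv input paths when `simulate = FALSE`.
#' @param out_dir output directory for report files.
#' @param preprocessing list: `window_points`, `poly_order`, `absorbance`.
#' @param qi list: `attributes` (columns entering Q_i) and `directions`
#'   (named vector of direction flags).
#' @param model list: `method` ("plsr", "ann" or "both"), `folds`,
#'   `max_components`, `hidden_units`, `maxit`, `decay`.
#' @param responses responses to calibrate (subset of the attribute
#'   columns plus `"qi"`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 42L, simulate = TRUE, n_total = 1000L,
                       noise_scale = 1,
                       spectra_csv = NULL, attributes_csv = NULL,
                       out_dir = tempfile("dateqi_run_"),
                       preprocessing = list(),
                       qi = list(),
                       model = list(),
                       responses = c("tss", "delta_e", "bi", "hardness",
                                     "mc", "qi")) {
  merge_block <- function(user, defaults, label) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      stop("run_config: unknown ", label, " key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(defaults, user)
  }
  preprocessing <- merge_block(preprocessing,
                               list(window_points = 15L, poly_order = 3L,
                                    absorbance = FALSE), "preprocessing")
  qi <- merge_block(qi, list(attributes = QI_DEFAULT_ATTRIBUTES,
                             directions = QI_DEFAULT_DIRECTIONS), "qi")
  model <- merge_block(model, list(method = "both", folds = 10L,
                                   max_components = 20L, hidden_units = 8L,
                                   maxit = 500L, decay = 1e-3), "model")
  if (!model$method %in% c("plsr", "ann", "both")) {
    stop("run_config: model$method must be 'plsr', 'ann' or 'both'",
         call. = FALSE)
  }
  missing_dir <- setdiff(qi$attributes, names(qi$directions))
  if (length(missing_dir)) {
    stop("run_config: no direction flag for attribute(s): ",
         paste(missing_dir, collapse = ", "), call. = FALSE)
  }
  if (!simulate && (is.null(spectra_csv) || is.null(attributes_csv))) {
    stop("run_config: simulate = FALSE requires spectra_csv and attributes_csv",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), simulate = isTRUE(simulate),
                 n_total = as.integer(n_total), noise_scale = noise_scale,
                 spectra_csv = spectra_csv, attributes_csv = attributes_csv,
                 out_dir = out_dir, preprocessing = preprocessing,
                 qi = qi, model = model, responses = responses),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys match [run_config()]
#'   arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("read_run_config: unknown key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$qi$directions)) raw$qi$directions <- unlist(raw$qi$directions)
  do.call(run_config, raw)
}

#' Average replicate scans and take the Savitzky-Golay second derivative
#'
#' Pipeline preprocessing stage: scans are averaged per fruit first (the
#' documented order), optionally converted to absorbance, then the second
#' derivative is taken row-wise.
#'
#' @param cohort a `fruit_cohort` (or a list with `scans`, `scan_info`,
#'   `grid` as returned by [read_spectra_csv()] plus sample grouping).
#' @param window_points,poly_order Savitzky-Golay settings.
#' @param absorbance convert averaged reflectance to absorbance before
#'   differentiating (default `FALSE`: derivative of reflectance).
#' @return List with `X` (fruits x wavelengths second-derivative matrix,
#'   rows named by sample), `sample_ids`, `grid`.
#' @export
preprocess_cohort <- function(cohort, window_points = 15L, poly_order = 3L,
                              absorbance = FALSE) {
  ids <- unique(cohort$scan_info$sample_id)
  grp <- factor(cohort$scan_info$sample_id, levels = ids)
  avg <- rowsum(cohort$scans, grp) / as.vector(table(grp))
  if (absorbance) {
    if (any(avg <= 0)) {
      stop("preprocess_cohort: non-positive reflectance; cannot convert to ",
           "absorbance", call. = FALSE)
    }
    avg <- log10(100 / avg)
  }
  X <- sg_second_derivative_matrix(avg, cohort$grid, window_points, poly_order)
  rownames(X) <- ids
  list(X = X, sample_ids = ids, grid = cohort$grid)
}

#' Normalization bounds estimated from a calibration table
#'
#' @param attributes data frame holding the attribute columns.
#' @param names attribute columns to bound.
#' @return Named list of [normalization_bounds()].
#' @export
estimate_bounds <- function(attributes, names = QI_DEFAULT_ATTRIBUTES) {
  out <- lapply(names, function(nm) {
    v <- attributes[[nm]]
    if (is.null(v)) stop("estimate_bounds: no column '", nm, "'", call. = FALSE)
    normalization_bounds(nm, min(v), max(v))
  })
  names(out) <- names
  out
}

#' Quality index for every fruit in an attribute table
#'
#' Normalizes the configured attribute columns against the supplied bounds
#' (clipping out-of-bound values, as happens when calibration bounds are
#' applied to new fruit) and averages them into Q_i.
#'
#' @param attributes data frame with one row per fruit.
#' @param bounds named list of [normalization_bounds()] (typically from
#'   [estimate_bounds()] on the calibration partition).
#' @param directions named character vector of direction flags.
#' @return The input data frame with columns `qi` and `n_attributes`
#'   appended.
#' @export
cohort_quality_index <- function(attributes, bounds,
                                 directions = QI_DEFAULT_DIRECTIONS) {
  normalized <- lapply(names(bounds), function(nm) {
    normalize_attribute(attributes[[nm]], bounds[[nm]],
                        attribute_spec(nm, directions[[nm]]))
  })
  names(normalized) <- names(bounds)
  qi <- compute_qi(normalized, sample_ids = attributes$sample_id)
  attributes$qi <- qi$qi
  attributes$n_attributes <- qi$n_attributes
  attributes
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", label, "] failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full calibration pipeline and write report files
#'
#' Stages: obtain the cohort (simulated or from CSV), preprocess spectra,
#' compute the quality index, fit the exponential shelf-life model, and
#' cross-validate a calibration per response and method. Writes
#' `metrics.csv` (one row per response/method with r2_cal, rmsec, r2_cv,
#' rmsecv), one model JSON per response/method, `shelf_life.json`
#' (including the persisted normalization bounds) and `run.log`. On any
#' stage error the partial outputs are removed.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with `metrics` (data frame), `models` (named
#'   list), `shelf_life`, `bounds`, `train` (the calibration cohort with
#'   Q_i appended) and `out_dir`.
#' @export
run_calibration <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail_cleanup <- function() unlink(written)

  result <- tryCatch({
    cohort <- stage("input", {
      if (cfg$simulate) {
        tc <- trajectory_config(seed = cfg$seed, noise_scale = cfg$noise_scale)
        make_dataset(cfg$n_total, tc)$train
      } else {
        read_cohort_csv(cfg$spectra_csv, cfg$attributes_csv)
      }
    })

    prep <- stage("preprocess", preprocess_cohort(
      cohort, cfg$preprocessing$window_points, cfg$preprocessing$poly_order,
      cfg$preprocessing$absorbance))

    bounds <- stage("qi", estimate_bounds(cohort$attributes, cfg$qi$attributes))
    attrs <- stage("qi", cohort_quality_index(cohort$attributes, bounds,
                                              cfg$qi$directions))

    shelf <- stage("shelf_life", fit_shelf_life(attrs$day, attrs$qi))

    methods <- if (cfg$model$method == "both") c("plsr", "ann") else cfg$model$method
    rows <- list(); models <- list()
    for (resp in cfg$responses) {
      y <- attrs[[resp]]
      if (is.null(y)) stop("stage [calibrate] failed: no response column '",
                           resp, "'", call. = FALSE)
      for (method in methods) {
        hyper <- if (method == "plsr") {
          ncomp <- stage("calibrate", select_components(
            prep$X, y, cfg$model$max_components, cfg$model$folds, cfg$seed))
          list(n_components = as.integer(ncomp))
        } else {
          list(hidden_units = cfg$model$hidden_units,
               maxit = cfg$model$maxit, decay = cfg$model$decay,
               seed = cfg$seed)
        }
        met <- stage("calibrate", cross_validate(
          method, prep$X, y, cfg$model$folds, hyper, cfg$seed))
        fitted <- stage("calibrate", if (method == "plsr") {
          plsr_fit(prep$X, y, hyper$n_components)
        } else {
          ann_fit(prep$X, y, hyper$hidden_units, hyper$seed, hyper$maxit,
                  hyper$decay)
        })
        key <- paste(resp, method, sep = "_")
        model_path <- file.path(cfg$out_dir, paste0("model_", key, ".json"))
        write_calibration_model(
          fitted, model_path, response = resp, metrics = met,
          preprocessing = c(cfg$preprocessing,
                            list(grid = unclass(prep$grid))))
        written <- c(written, model_path)
        models[[key]] <- fitted
        rows[[key]] <- data.frame(
          response = resp, method = method,
          r2_cal = met$r_squared, rmsec = met$rmsec,
          r2_cv = met$r_squared_cv, rmsecv = met$rmsecv,
          n_components_or_units = met$n_components_or_units,
          stringsAsFactors = FALSE)
      }
    }
    metrics <- do.call(rbind, rows)
    rownames(metrics) <- NULL

    metrics_path <- file.path(cfg$out_dir, "metrics.csv")
    utils::write.csv(metrics, metrics_path, row.names = FALSE)
    shelf_path <- file.path(cfg$out_dir, "shelf_life.json")
    write_shelf_life_model(shelf, shelf_path, bounds = bounds)
    log_path <- file.path(cfg$out_dir, "run.log")
    writeLines(c(
      sprintf("dateqi %s", as.character(utils::packageVersion("dateqi"))),
      sprintf("R %s", getRversion()),
      sprintf("seed: %d", cfg$seed),
      sprintf("n fruits (calibration): %d", nrow(attrs)),
      sprintf("responses: %s", paste(cfg$responses, collapse = ", ")),
      sprintf("methods: %s", paste(methods, collapse = ", ")),
      sprintf("config hash: %s", config_hash(cfg))), log_path)
    written <- c(written, metrics_path, shelf_path, log_path)

    list(metrics = metrics, models = models, shelf_life = shelf,
         bounds = bounds, train = attrs, out_dir = cfg$out_dir)
  }, error = function(e) {
    on_fail_cleanup()
    stop(e)
  })
  invisible(result)
}

#' Read a cohort from the package's CSV dialects
#'
#' @param spectra_csv wide spectra CSV (see [read_spectra_csv()]).
#' @param attributes_csv per-fruit attribute CSV.
#' @return A `fruit_cohort`-shaped list.
#' @export
read_cohort_csv <- function(spectra_csv, attributes_csv) {
  sp <- read_spectra_csv(spectra_csv)
  attrs <- utils::read.csv(attributes_csv, stringsAsFactors = FALSE)
  structure(list(attributes = attrs, scans = sp$values,
                 scan_info = sp$data, grid = sp$grid, cfg = NULL),
            class = "fruit_cohort")
}

#' Predict responses for new spectra from persisted models
#'
#' Loads one or more model JSON files, checks that the new spectra share
#' the training grid, applies the preprocessing recorded in each model
#' file, and writes one prediction column per model.
#'
#' @param model_paths character vector of model JSON paths.
#' @param spectra_csv wide spectra CSV of the new scans.
#' @param out_csv output path; one row per fruit, one column per response.
#' @return The predictions data frame, invisibly.
#' @export
run_prediction <- function(model_paths, spectra_csv, out_csv) {
  sp <- read_spectra_csv(spectra_csv)
  docs <- lapply(model_paths, read_calibration_model)

  if (nrow(sp$values) == 0L) {
    warning("run_prediction: empty input; writing header only", call. = FALSE)
    empty <- data.frame(sample_id = character(0))
    for (d in docs) empty[[paste(d$response, d$metrics$method %||% "",
                                 sep = "_")]] <- numeric(0)
    utils::write.csv(empty, out_csv, row.names = FALSE)
    return(invisible(empty))
  }

  cohort <- structure(list(scans = sp$values, scan_info = sp$data,
                           grid = sp$grid), class = "fruit_cohort")
  out <- NULL
  for (d in docs) {
    pp <- d$preprocessing
    if (!is.null(pp$grid)) {
      g <- pp$grid
      if (g$n_points != sp$grid$n_points ||
          abs(g$start_nm - sp$grid$start_nm) > 1e-6 ||
          abs(g$step_nm - sp$grid$step_nm) > 1e-6) {
        stop("run_prediction: grid mismatch; model expects ", g$n_points,
             " points from ", g$start_nm, " nm at ", g$step_nm,
             " nm spacing", call. = FALSE)
      }
    }
    prep <- preprocess_cohort(cohort,
                              pp$window_points %||% 15L,
                              pp$poly_order %||% 3L,
                              isTRUE(pp$absorbance))
    pred <- calibration_predict(d$model, prep$X)
    if (is.null(out)) {
      out <- data.frame(sample_id = prep$sample_ids, stringsAsFactors = FALSE)
    }
    out[[d$response]] <- pred
  }
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}
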