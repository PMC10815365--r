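#' Declare a quality attribute and its direction
#'
#' Every attribute entering the quality index must state whether larger
#' values mean better fruit (`"quality_increasing"`, e.g. hardness, moisture
#' content, hedonic scores) or worse fruit (`"quality_decreasing"`, e.g.
#' TSS, colour difference, browning index, which all rise as the fruit
#' deteriorates). Decreasing attributes are inverted during normalization so
#' that the composite index always falls as quality is lost.
#'
#' @param name attribute name (unique within a dataset).
#' @param direction `"quality_increasing"` or `"quality_decreasing"`.
#' @param units optional unit label (e.g. `"N"`, `"%"`).
#' @return An `attribute_spec` object.
#' @export
attribute_spec <- function(name,
                           direction = c("quality_increasing",
                                         "quality_decreasing"),
                           units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  direction <- match.arg(direction)
  structure(list(name = name, direction = direction, units = units),
            class = "attribute_spec")
}

#' Min-max normalization bounds for one attribute
#'
#' @param attribute attribute name.
#' @param x_min,x_max bounds; `x_max` must exceed `x_min`.
#' @return A `normalization_bounds` object.
#' @export
normalization_bounds <- function(attribute, x_min, x_max) {
  stopifnot(is.character(attribute), length(attribute) == 1L)
  if (!is.finite(x_min) || !is.finite(x_max)) {
    stop("normalization_bounds: x_min and x_max must be finite", call. = FALSE)
  }
  if (x_max <= x_min) {
    stop("normalization_bounds: need x_max > x_min (got [", x_min, ", ",
         x_max, "] for '", attribute, "')", call. = FALSE)
  }
  structure(list(attribute = attribute,
                 x_min = as.numeric(x_min), x_max = as.numeric(x_max)),
            class = "normalization_bounds")
}

#' Min-max normalize an attribute to [0, 1]
#'
#' Maps raw values to \eqn{\hat{x} = (x - x_{min}) / (x_{max} - x_{min})}
#' for quality-increasing attributes, and to \eqn{1 - \hat{x}} for
#' quality-decreasing ones, so that 1 always means "best" regardless of the
#' attribute's raw direction. Values outside the bounds (as happens when
#' bounds estimated on a calibration set are applied to new fruit) are
#' clipped into range with a warning.
#'
#' @param values numeric vector of raw attribute values.
#' @param bounds a [normalization_bounds()] object.
#' @param spec an [attribute_spec()] giving the direction flag.
#' @return Numeric vector in \[0, 1\], same length as `values`.
#' @examples
#' sp <- attribute_spec("hardness", "quality_increasing", "N")
#' b <- normalization_bounds("hardness", 73.59, 99.81)
#' normalize_attribute(c(99.81, 73.59), b, sp)
#' @export
normalize_attribute <- function(values, bounds, spec) {
  stopifnot(inherits(bounds, "normalization_bounds"),
            inherits(spec, "attribute_spec"))
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop("normalize_attribute: values must be finite numerics", call. = FALSE)
  }
  out_of_range <- values < bounds$x_min | values > bounds$x_max
  if (any(out_of_range)) {
    warning(sprintf("normalize_attribute('%s'): %d value(s) outside [%g, %g] clipped",
                    spec$name, sum(out_of_range), bounds$x_min, bounds$x_max),
            call. = FALSE)
    values <- pmin(pmax(values, bounds$x_min), bounds$x_max)
  }
  xhat <- (values - bounds$x_min) / (bounds$x_max - bounds$x_min)
  if (spec$direction == "quality_decreasing") 1 - xhat else xhat
}

#' Composite quality index from normalized attributes
#'
#' The quality index Q_i of a sample is the arithmetic mean of its
#' normalized attribute values, so it lies in \[0, 1\] whenever the inputs
#' do, and is invariant to the order in which attributes are supplied.
#'
#' @param normalized named list (or data.frame) of numeric vectors, one per
#'   attribute, all the same length and all in \[0, 1\].
#' @param sample_ids optional character vector of sample labels.
#' @return A data.frame with columns `sample_id`, `qi`, `n_attributes`.
#' @examples
#' compute_qi(list(a = c(0.2, 1), b = c(0.6, 1)))
#' @export
compute_qi <- function(normalized, sample_ids = NULL) {
  if (is.data.frame(normalized)) normalized <- as.list(normalized)
  if (!is.list(normalized) || length(normalized) == 0L) {
    stop("compute_qi: need a non-empty list of attribute vectors", call. = FALSE)
  }
  lens <- vapply(normalized, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("compute_qi: attribute vectors have unequal lengths (",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  }
  mat <- do.call(cbind, normalized)
  if (anyNA(mat) || any(mat < 0 | mat > 1)) {
    stop("compute_qi: all normalized values must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(mat)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  stopifnot(length(sample_ids) == n)
  data.frame(sample_id = sample_ids,
             qi = rowMeans(mat),
             n_attributes = ncol(mat),
             stringsAsFactors = FALSE)
}

#' Fit the exponential shelf-life decay model
#'
#' Fits \eqn{Q_i(t) = A e^{-k t}} to quality-index observations by nonlinear
#' least squares on the original scale (Levenberg-Marquardt), initialized by
#' ordinary least squares on \eqn{\log Q_i}. Points with non-positive Q_i
#' are excluded from the initializer only. R-squared is computed on the
#' original scale.
#'
#' A flat series is handled as the degenerate fit `decay_rate = 0`,
#' `amplitude = mean(qi)`.
#'
#' @param days numeric vector of storage days (non-negative); at least 3
#'   distinct values are required.
#' @param qi quality-index observations, same length as `days`.
#' @return A `shelf_life_model` with fields `amplitude`, `decay_rate`,
#'   `r_squared`, `n_obs`.
#' @examples
#' d <- seq(0, 120, by = 20)
#' m <- fit_shelf_life(d, 0.87 * exp(-0.01 * d))
#' predict_qi(m, 60)
#' @export
fit_shelf_life <- function(days, qi) {
  stopifnot(is.numeric(days), is.numeric(qi), length(days) == length(qi))
  if (anyNA(days) || anyNA(qi) || any(days < 0)) {
    stop("fit_shelf_life: days must be non-negative and inputs NA-free",
         call. = FALSE)
  }
  if (length(unique(days)) < 3L) {
    stop("fit_shelf_life: need at least 3 distinct day values", call. = FALSE)
  }

  # log-linear initializer on the positive observations
  pos <- qi > 0
  if (sum(pos) >= 2L && length(unique(days[pos])) >= 2L) {
    ini <- stats::lm.fit(cbind(1, days[pos]), log(qi[pos]))$coefficients
    A0 <- exp(ini[[1]])
    k0 <- max(0, -ini[[2]])
  } else {
    A0 <- max(mean(qi), .Machine$double.eps)
    k0 <- 0
  }

  sse <- function(p) sum((qi - p[1] * exp(-p[2] * days))^2)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      qi ~ A * exp(-k * day),
      data = data.frame(qi = qi, day = days),
      start = list(A = A0, k = k0),
      lower = c(A = .Machine$double.eps, k = 0),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-10))
    stats::coef(m)
  }, error = function(e) c(A = A0, k = k0))

  # polish (and fallback) with a quasi-Newton pass on the raw loss
  opt <- stats::optim(fit, sse, method = "L-BFGS-B",
                      lower = c(.Machine$double.eps, 0),
                      control = list(factr = 1e1, maxit = 10000))
  if (opt$value < sse(fit)) fit <- opt$par

  pred <- fit[[1]] * exp(-fit[[2]] * days)
  ss_tot <- sum((qi - mean(qi))^2)
  r2 <- if (ss_tot > 0) 1 - sum((qi - pred)^2) / ss_tot else 1
  structure(list(amplitude = unname(fit[[1]]),
                 decay_rate = unname(fit[[2]]),
                 r_squared = r2,
                 n_obs = length(qi)),
            class = "shelf_life_model")
}

#' Construct a shelf-life model from known parameters
#'
#' Useful for evaluating a published decay model (for Khalal-stage dates
#' under controlled-atmosphere storage, amplitude 0.87 and rate 0.01 per
#' day) without refitting.
#'
#' @param amplitude Q_i at day 0 (> 0).
#' @param decay_rate first-order decay rate per day (>= 0).
#' @param r_squared optional goodness of fit to carry along.
#' @return A `shelf_life_model`.
#' @export
shelf_life_model <- function(amplitude, decay_rate, r_squared = NA_real_) {
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("shelf_life_model: amplitude must be > 0", call. = FALSE)
  }
  if (!is.finite(decay_rate) || decay_rate < 0) {
    stop("shelf_life_model: decay_rate must be >= 0", call. = FALSE)
  }
  structure(list(amplitude = amplitude, decay_rate = decay_rate,
                 r_squared = r_squared, n_obs = NA_integer_),
            class = "shelf_life_model")
}

#' @export
print.shelf_life_model <- function(x, ...) {
  cat(sprintf("Exponential shelf-life model: Qi = %.4g * exp(-%.4g * day)\n",
              x$amplitude, x$decay_rate))
  if (is.finite(x$r_squared)) cat(sprintf("  R-squared = %.4f\n", x$r_squared))
  invisible(x)
}

#' Predict the quality index at a storage day
#'
#' @param model a `shelf_life_model`.
#' @param day non-negative storage day(s).
#' @return Predicted Q_i, `amplitude * exp(-decay_rate * day)`.
#' @examples
#' predict_qi(shelf_life_model(0.87, 0.01), c(0, 100))
#' @export
predict_qi <- function(model, day) {
  stopifnot(inherits(model, "shelf_life_model"))
  if (!is.numeric(day) || anyNA(day) || any(day < 0)) {
    stop("predict_qi: day must be non-negative", call. = FALSE)
  }
  model$amplitude * exp(-model$decay_rate * day)
}

#' @export
predict.shelf_life_model <- function(object, day, ...) predict_qi(object, day)

#' Save / load a shelf-life model (with normalization bounds) as JSON
#'
#' @param model a `shelf_life_model`.
#' @param path file path for the JSON document.
#' @param bounds optional list of [normalization_bounds()] persisted with
#'   the model so that new data can be normalized identically.
#' @return `write_shelf_life_model` returns `path` invisibly;
#'   `read_shelf_life_model` returns a list with elements `model` and
#'   `bounds`.
#' @export
write_shelf_life_model <- function(model, path, bounds = list()) {
  stopifnot(inherits(model, "shelf_life_model"))
  doc <- list(amplitude = model$amplitude,
              decay_rate = model$decay_rate,
              r_squared = model$r_squared,
              bounds = lapply(bounds, function(b) {
                list(attribute = b$attribute, x_min = b$x_min, x_max = b$x_max)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shelf_life_model
#' @export
read_shelf_life_model <- function(path) {
  doc <- jsonlite::read_json(path)
  model <- shelf_life_model(doc$amplitude, doc$decay_rate,
                            r_squared = doc$r_squared %||% NA_real_)
  bounds <- lapply(doc$bounds, function(b) {
    normalization_bounds(b$attribute, b$x_min, b$x_max)
  })
  list(model = model, bounds = bounds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
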