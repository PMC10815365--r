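#' Uniform wavelength grid
#'
#' The portable VIS-NIR instrument emulated here records reflectance from
#' 285 to 1200 nm at 3 nm steps (306 points); that is the default grid.
#'
#' @param start_nm first wavelength (nm).
#' @param step_nm grid spacing (nm), > 0.
#' @param n_points number of points.
#' @return A `wavelength_grid` with fields `start_nm`, `stop_nm`, `step_nm`,
#'   `n_points`.
#' @export
wavelength_grid <- function(start_nm = 285, step_nm = 3, n_points = 306) {
  stopifnot(is.finite(start_nm), is.finite(step_nm), step_nm > 0,
            n_points >= 1, n_points == as.integer(n_points))
  structure(list(start_nm = as.numeric(start_nm),
                 stop_nm = start_nm + (n_points - 1) * step_nm,
                 step_nm = as.numeric(step_nm),
                 n_points = as.integer(n_points)),
            class = "wavelength_grid")
}

#' Wavelengths of a grid
#' @param grid a `wavelength_grid`.
#' @return Numeric vector of wavelengths in nm.
#' @export
grid_wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  grid$start_nm + grid$step_nm * (seq_len(grid$n_points) - 1)
}

#' Validate raw wavelengths as a uniform grid
#'
#' Accepts a strictly increasing, uniformly spaced wavelength vector (to
#' within 1e-6 nm) and returns the corresponding [wavelength_grid()].
#' Non-uniform inputs are rejected; resampling is out of scope.
#'
#' @param wavelengths numeric vector of wavelengths in nm.
#' @return A `wavelength_grid`.
#' @examples
#' validate_grid(seq(285, 1200, by = 3))
#' @export
validate_grid <- function(wavelengths) {
  if (!is.numeric(wavelengths) || length(wavelengths) < 2L) {
    stop("validate_grid: need at least two wavelengths", call. = FALSE)
  }
  d <- diff(wavelengths)
  if (any(d <= 0)) {
    stop("validate_grid: wavelengths must be strictly increasing", call. = FALSE)
  }
  if (max(d) - min(d) > 1e-6) {
    stop("validate_grid: spacing is not uniform (range ",
         signif(min(d), 8), " to ", signif(max(d), 8),
         " nm); resampling is not supported", call. = FALSE)
  }
  wavelength_grid(wavelengths[1], mean(d), length(wavelengths))
}

SPECTRUM_KINDS <- c("reflectance_percent", "absorbance", "second_derivative")

#' A single spectrum on a wavelength grid
#'
#' @param values numeric vector, one value per grid point; must be finite.
#'   For `kind = "reflectance_percent"` values must lie in \[0, 100\].
#' @param grid a [wavelength_grid()].
#' @param kind one of `"reflectance_percent"`, `"absorbance"`,
#'   `"second_derivative"`.
#' @param sample_id sample label.
#' @return A `spectrum` object.
#' @export
new_spectrum <- function(values, grid = wavelength_grid(),
                         kind = "reflectance_percent", sample_id = "sample") {
  stopifnot(inherits(grid, "wavelength_grid"))
  kind <- match.arg(kind, SPECTRUM_KINDS)
  if (!is.numeric(values) || length(values) != grid$n_points) {
    stop("new_spectrum: values must be numeric of length grid$n_points (",
         grid$n_points, ")", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("new_spectrum: non-finite values not allowed", call. = FALSE)
  }
  if (kind == "reflectance_percent" && (any(values < 0) || any(values > 100))) {
    stop("new_spectrum: reflectance_percent values must lie in [0, 100]",
         call. = FALSE)
  }
  structure(list(grid = grid, values = as.numeric(values), kind = kind,
                 sample_id = as.character(sample_id)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %s, %d points (%g-%g nm @ %g nm)\n",
              x$sample_id, x$kind, x$grid$n_points, x$grid$start_nm,
              x$grid$stop_nm, x$grid$step_nm))
  invisible(x)
}

same_grid <- function(g1, g2) {
  isTRUE(all.equal(unclass(g1), unclass(g2), tolerance = 1e-9))
}

#' Average replicate scans of one sample
#'
#' Instruments capture several scans per fruit and average them to suppress
#' shot noise; this is the pointwise arithmetic mean. All scans must share
#' the grid, kind and sample id.
#'
#' @param scans a list of [new_spectrum()] objects (>= 1).
#' @return A single `spectrum` of the same kind and grid.
#' @export
average_scans <- function(scans) {
  if (!is.list(scans) || length(scans) == 0L ||
      !all(vapply(scans, inherits, logical(1), "spectrum"))) {
    stop("average_scans: need a non-empty list of spectrum objects",
         call. = FALSE)
  }
  first <- scans[[1]]
  for (s in scans[-1]) {
    if (!same_grid(s$grid, first$grid) || s$kind != first$kind ||
        s$sample_id != first$sample_id) {
      stop("average_scans: scans differ in grid, kind or sample_id",
           call. = FALSE)
    }
  }
  vals <- rowMeans(vapply(scans, `[[`, numeric(first$grid$n_points), "values"))
  new_spectrum(vals, first$grid, first$kind, first$sample_id)
}

#' Convert percent reflectance to absorbance
#'
#' Uses the standard NIR convention \eqn{A = \log_{10}(1/R)} with R as a
#' fraction, i.e. \eqn{A = \log_{10}(100 / R\%)}. All reflectance values
#' must be strictly positive.
#'
#' @param s a `spectrum` of kind `"reflectance_percent"`.
#' @return A `spectrum` of kind `"absorbance"`.
#' @export
to_absorbance <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (s$kind != "reflectance_percent") {
    stop("to_absorbance: input must be a reflectance_percent spectrum",
         call. = FALSE)
  }
  bad <- which(s$values <= 0)
  if (length(bad)) {
    wl <- grid_wavelengths(s$grid)
    stop("to_absorbance: non-positive reflectance at wavelength(s) ",
         paste(utils::head(wl[bad], 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", " nm", call. = FALSE)
  }
  new_spectrum(log10(100 / s$values), s$grid, "absorbance", s$sample_id)
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' At each point a polynomial of degree `poly_order` is least-squares
#' fitted over a centred window of `window_points` grid points and its
#' second derivative evaluated at the centre; near the edges, one-sided
#' windows of the same length are used so the output has the input's
#' length. Results are scaled by the physical grid spacing (units per nm^2)
#' so they are grid-independent.
#'
#' Defaults (window 15 points = 45 nm at 3 nm spacing, cubic polynomial)
#' are wide enough to suppress instrument noise while preserving pigment
#' and water band structure.
#'
#' @param s a `spectrum` (any kind).
#' @param window_points odd window length, >= `poly_order + 1`.
#' @param poly_order polynomial degree, >= 2.
#' @return A `spectrum` of kind `"second_derivative"`.
#' @examples
#' g <- wavelength_grid()
#' s <- new_spectrum(50 + 20 * sin(grid_wavelengths(g) / 80), g)
#' d2 <- sg_second_derivative(s)
#' @export
sg_second_derivative <- function(s, window_points = 15L, poly_order = 3L) {
  stopifnot(inherits(s, "spectrum"))
  check_sg_args(s$grid$n_points, window_points, poly_order)
  vals <- signal::sgolayfilt(s$values, p = poly_order, n = window_points,
                             m = 2, ts = s$grid$step_nm)
  new_spectrum(vals, s$grid, "second_derivative", s$sample_id)
}

check_sg_args <- function(n_points, window_points, poly_order) {
  if (poly_order < 2) {
    stop("sg_second_derivative: poly_order must be >= 2 for a second derivative",
         call. = FALSE)
  }
  if (window_points %% 2 == 0 || window_points < poly_order + 1) {
    stop("sg_second_derivative: window_points must be odd and >= poly_order + 1",
         call. = FALSE)
  }
  if (window_points > n_points) {
    stop("sg_second_derivative: window (", window_points,
         ") exceeds spectrum length (", n_points, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Savitzky-Golay second derivative of a spectra matrix
#'
#' Row-wise variant of [sg_second_derivative()] for a cohort stored as a
#' samples-by-wavelengths matrix.
#'
#' @param mat numeric matrix, rows = samples, columns = grid points.
#' @param grid the shared [wavelength_grid()].
#' @inheritParams sg_second_derivative
#' @return Matrix of the same shape with second-derivative values.
#' @export
sg_second_derivative_matrix <- function(mat, grid, window_points = 15L,
                                        poly_order = 3L) {
  stopifnot(is.matrix(mat), inherits(grid, "wavelength_grid"),
            ncol(mat) == grid$n_points)
  check_sg_args(grid$n_points, window_points, poly_order)
  out <- t(apply(mat, 1, signal::sgolayfilt, p = poly_order,
                 n = window_points, m = 2, ts = grid$step_nm))
  dimnames(out) <- dimnames(mat)
  out
}

# ---- CSV dialect -----------------------------------------------------------
# Wide spectra table: sample_id, scan_no, [kind,] wl_285, wl_288, ..., wl_1200

#' Read / write wide-format spectra CSV
#'
#' The on-disk dialect is one row per scan with columns `sample_id`,
#' `scan_no`, an optional `kind`, and one `wl_<nm>` column per wavelength.
#'
#' @param path CSV file path.
#' @return `read_spectra_csv` returns a list with `data` (data.frame of
#'   sample_id/scan_no/kind), `values` (numeric matrix) and `grid`.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wl_cols <- grep("^wl_", names(df), value = TRUE)
  if (length(wl_cols) < 2L) {
    stop("read_spectra_csv: no wl_<nm> columns found in ", path, call. = FALSE)
  }
  wl <- as.numeric(sub("^wl_", "", wl_cols))
  grid <- validate_grid(wl)
  meta <- df[setdiff(names(df), wl_cols)]
  if (is.null(meta$kind)) meta$kind <- "reflectance_percent"
  if (is.null(meta$scan_no)) meta$scan_no <- 1L
  vals <- as.matrix(df[wl_cols])
  storage.mode(vals) <- "double"
  list(data = meta, values = vals, grid = grid)
}

#' @rdname read_spectra_csv
#' @param values samples-by-wavelengths matrix.
#' @param grid the [wavelength_grid()] labelling the columns.
#' @param sample_id,scan_no,kind per-row metadata vectors (recycled).
#' @export
write_spectra_csv <- function(path, values, grid, sample_id,
                              scan_no = 1L, kind = "reflectance_percent") {
  stopifnot(is.matrix(values), ncol(values) == grid$n_points)
  wl <- grid_wavelengths(grid)
  n <- nrow(values)
  df <- data.frame(sample_id = rep_len(as.character(sample_id), n),
                   scan_no = rep_len(scan_no, n),
                   kind = rep_len(kind, n),
                   stringsAsFactors = FALSE)
  spec_df <- as.data.frame(values)
  names(spec_df) <- paste0("wl_", format(wl, trim = TRUE, scientific = FALSE))
  utils::write.csv(cbind(df, spec_df), path, row.names = FALSE)
  invisible(path)
}
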