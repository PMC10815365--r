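#' Coefficient of determination and root-mean-square error
#'
#' `r_squared` is the coefficient of determination
#' \eqn{1 - SS_{res}/SS_{tot}} (not squared Pearson correlation; the two
#' coincide for least-squares fits evaluated on their own training data).
#' It is undefined for a constant `y_true`.
#'
#' @param y_true observed values.
#' @param y_pred predicted values, same length (>= 2).
#' @return List with elements `r_squared` and `rmse`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 2, 2)) # R2 = 0
#' @export
compute_metrics <- function(y_true, y_pred) {
  stopifnot(is.numeric(y_true), is.numeric(y_pred))
  if (length(y_true) != length(y_pred) || length(y_true) < 2L) {
    stop("compute_metrics: y_true and y_pred must have equal length >= 2",
         call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop("compute_metrics: y_true is constant, R-squared undefined",
         call. = FALSE)
  }
  ss_res <- sum((y_true - y_pred)^2)
  list(r_squared = 1 - ss_res / ss_tot,
       rmse = sqrt(mean((y_true - y_pred)^2)))
}

make_folds <- function(n, folds, seed) {
  if (folds < 2L) stop("cross_validate: folds must be >= 2", call. = FALSE)
  if (n < folds) stop("cross_validate: fewer samples than folds", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  idx <- sample.int(n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  assignment <- integer(n)
  assignment[idx] <- rep_len(seq_len(folds), n)
  sizes <- tabulate(assignment, folds)
  if (any(sizes < 2L)) {
    stop("cross_validate: a fold would hold fewer than 2 samples", call. = FALSE)
  }
  assignment
}

fit_predict <- function(method, X_tr, y_tr, X_te, hyper) {
  if (method == "plsr") {
    ncomp <- min(hyper$n_components %||% 10L, nrow(X_tr) - 1L, ncol(X_tr))
    m <- plsr_fit(X_tr, y_tr, ncomp)
    plsr_predict(m, X_te)
  } else {
    m <- ann_fit(X_tr, y_tr,
                 hidden_units = hyper$hidden_units %||% 8L,
                 seed = hyper$seed %||% 1L,
                 maxit = hyper$maxit %||% 500L,
                 decay = hyper$decay %||% 1e-3)
    ann_predict(m, X_te)
  }
}

#' k-fold cross-validation of a chemometric calibration
#'
#' Samples are shuffled with the given seed and dealt into `folds` folds;
#' each fold is predicted by a model trained on the remaining folds, and
#' RMSECV is the root-mean-square error pooled over all held-out
#' predictions. Calibration metrics (RMSEC and R-squared) come from a final
#' fit on all data — calibration and cross-validation never share a
#' partition.
#'
#' @param method `"plsr"` or `"ann"`.
#' @param X predictor matrix (samples x wavelengths).
#' @param y response vector.
#' @param folds number of folds (default 10).
#' @param hyper named list of hyperparameters: `n_components` for PLSR;
#'   `hidden_units`, `maxit`, `decay` for the ANN.
#' @param seed integer seed for the fold shuffle (and ANN initialization).
#' @return A `calibration_metrics` object: `r_squared` and `rmsec` from the
#'   full-data fit, `r_squared_cv` and `rmsecv` from pooled held-out
#'   predictions, plus `n_components_or_units`, `folds`, `seed`, `method`
#'   and the final fitted `model`.
#' @export
cross_validate <- function(method = c("plsr", "ann"), X, y, folds = 10L,
                           hyper = list(), seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  assignment <- make_folds(nrow(X), folds, seed)
  if (method == "ann") hyper$seed <- hyper$seed %||% seed

  cv_pred <- numeric(length(y))
  for (f in seq_len(max(assignment))) {
    hold <- assignment == f
    cv_pred[hold] <- fit_predict(method, X[!hold, , drop = FALSE], y[!hold],
                                 X[hold, , drop = FALSE], hyper)
  }
  cv <- compute_metrics(y, cv_pred)

  final_pred <- fit_predict(method, X, y, X, hyper)
  cal <- compute_metrics(y, final_pred)

  n_cu <- if (method == "plsr") {
    min(hyper$n_components %||% 10L, nrow(X) - 1L, ncol(X))
  } else {
    hyper$hidden_units %||% 8L
  }
  structure(list(method = method,
                 r_squared = cal$r_squared, rmsec = cal$rmse,
                 r_squared_cv = cv$r_squared, rmsecv = cv$rmse,
                 n_components_or_units = as.integer(n_cu),
                 folds = as.integer(folds), seed = as.integer(seed),
                 cv_predictions = cv_pred),
            class = "calibration_metrics")
}

#' @export
print.calibration_metrics <- function(x, ...) {
  cat(sprintf("%s calibration (%d folds, seed %d):\n", toupper(x$method),
              x$folds, x$seed))
  cat(sprintf("  calibration:      R2 = %.3f, RMSEC  = %.4g\n",
              x$r_squared, x$rmsec))
  cat(sprintf("  cross-validation: R2 = %.3f, RMSECV = %.4g\n",
              x$r_squared_cv, x$rmsecv))
  invisible(x)
}

#' Choose the PLSR component count by minimum RMSECV
#'
#' Cross-validates a single PLSR fit per fold at the maximal component
#' count and reads held-out predictions for every truncated model off the
#' coefficient path, then returns the component count with the smallest
#' RMSECV. Ties break toward fewer components.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param max_components largest component count to consider (capped at
#'   what the fold training sets support).
#' @param folds number of folds (default 10).
#' @param seed fold-shuffle seed.
#' @return The selected component count (positive integer) with the RMSECV
#'   profile attached as attribute `"rmsecv"`.
#' @export
select_components <- function(X, y, max_components, folds = 10L, seed = 1L) {
  stopifnot(max_components >= 1)
  X <- as.matrix(X); y <- as.numeric(y)
  assignment <- make_folds(nrow(X), folds, seed)
  min_train <- min(tabulate(assignment) * -1 + nrow(X))
  kmax <- min(max_components, min_train - 1L, ncol(X))
  preds <- matrix(NA_real_, length(y), kmax)
  for (f in seq_len(max(assignment))) {
    hold <- assignment == f
    m <- plsr_fit(X[!hold, , drop = FALSE], y[!hold], kmax)
    for (k in seq_len(kmax)) {
      # if extraction stopped early (rank collapse), deeper counts reuse
      # the deepest achieved model
      preds[hold, k] <- plsr_predict(m, X[hold, , drop = FALSE],
                                     ncomp = min(k, m$n_components))
    }
  }
  rmsecv <- sqrt(colMeans((preds - y)^2))
  best <- which.min(rmsecv)   # which.min takes the first minimum: fewer LVs
  structure(as.integer(best), rmsecv = rmsecv)
}
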