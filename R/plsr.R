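#' Partial least squares regression (NIPALS, single response)
#'
#' Sequentially extracts latent variables: each component's weight vector
#' maximizes covariance between the X scores and the current response
#' residual; X and y are then deflated by the component's contribution.
#' Data are mean-centred (no scaling). The model stores the coefficient
#' path, i.e. the regression vector for every component count
#' `1..n_components`, so truncated-model predictions cost nothing extra.
#'
#' Extraction stops early (with the achieved number of components recorded)
#' if the weight vector norm collapses below `1e-12`, which signals that X
#' carries no further covariance with the response.
#'
#' @param X numeric matrix, samples x predictors (e.g. second-derivative
#'   spectra); no non-finite entries.
#' @param y numeric response vector, `length(y) == nrow(X)`.
#' @param n_components number of latent variables to extract; must satisfy
#'   `n_components <= min(nrow(X) - 1, ncol(X))`.
#' @return A `plsr_model` with fields `n_components` (achieved), `x_mean`,
#'   `y_mean`, `weights`, `x_loadings`, `y_loadings` (per component),
#'   `scores`, `coef_path` (predictors x components matrix) and
#'   `regression_vector` (final column of the path).
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, -2, 0.5) + rnorm(20, sd = 0.01)
#' m <- plsr_fit(X, y, 3)
#' head(plsr_predict(m, X))
#' @export
plsr_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("plsr_fit: X and y must be finite", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("plsr_fit: length(y) must equal nrow(X)", call. = FALSE)
  if (n_components < 1 || n_components > min(n - 1, p)) {
    stop("plsr_fit: n_components must lie in [1, min(nrow(X)-1, ncol(X))]",
         call. = FALSE)
  }

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)   # X residual, deflated per component
  f <- y - y_mean            # y residual

  W <- P <- matrix(0, p, n_components)
  Q <- numeric(n_components)
  TT <- matrix(0, n, n_components)
  achieved <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_sc <- as.numeric(E %*% w)
    tt <- sum(t_sc^2)
    if (tt < 1e-24) break
    p_load <- as.numeric(crossprod(E, t_sc)) / tt
    q_load <- sum(f * t_sc) / tt
    E <- E - tcrossprod(t_sc, p_load)
    f <- f - q_load * t_sc
    W[, a] <- w; P[, a] <- p_load; Q[a] <- q_load; TT[, a] <- t_sc
    achieved <- a
  }
  if (achieved == 0L) {
    stop("plsr_fit: response has no covariance with X (rank collapse at ",
         "component 1)", call. = FALSE)
  }
  W <- W[, seq_len(achieved), drop = FALSE]
  P <- P[, seq_len(achieved), drop = FALSE]
  Q <- Q[seq_len(achieved)]
  TT <- TT[, seq_len(achieved), drop = FALSE]

  # coefficient path: B_k = W_k (P_k' W_k)^{-1} q_{1:k} for k = 1..achieved.
  # P'W is unit upper triangular, so the solves are cheap and stable.
  PW <- crossprod(P, W)
  coef_path <- matrix(0, p, achieved)
  for (k in seq_len(achieved)) {
    coef_path[, k] <- W[, 1:k, drop = FALSE] %*%
      backsolve(PW[1:k, 1:k, drop = FALSE], Q[1:k])
  }

  structure(list(n_components = achieved,
                 requested_components = n_components,
                 x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = Q,
                 scores = TT,
                 coef_path = coef_path,
                 regression_vector = coef_path[, achieved]),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("PLSR model: %d latent variable(s), %d predictors\n",
              x$n_components, length(x$x_mean)))
  invisible(x)
}

#' Predict from a fitted PLSR model
#'
#' @param m a [plsr_fit()] model.
#' @param X new predictor matrix with the training column count.
#' @param ncomp number of latent variables to use (default: all achieved).
#' @return Numeric vector of predictions `(X - x_mean) b + y_mean`.
#' @export
plsr_predict <- function(m, X, ncomp = NULL) {
  stopifnot(inherits(m, "plsr_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(m$x_mean)) {
    stop("plsr_predict: X has ", ncol(X), " columns, model expects ",
         length(m$x_mean), call. = FALSE)
  }
  if (is.null(ncomp)) ncomp <- m$n_components
  if (ncomp < 1 || ncomp > m$n_components) {
    stop("plsr_predict: ncomp out of range [1, ", m$n_components, "]",
         call. = FALSE)
  }
  b <- m$coef_path[, ncomp]
  as.numeric(sweep(X, 2, m$x_mean) %*% b) + m$y_mean
}

#' @export
predict.plsr_model <- function(object, newdata, ncomp = NULL, ...) {
  plsr_predict(object, newdata, ncomp)
}
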