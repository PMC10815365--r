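#' Single-hidden-layer neural-network calibration
#'
#' Feed-forward regressor with one hidden layer, trained by quasi-Newton
#' (BFGS) optimization of the penalized squared-error loss via
#' [nnet::nnet()]. Inputs are standardized per column and the response is
#' standardized too (both restored at prediction time), which keeps the
#' optimization well conditioned across responses of very different scales
#' (hardness in newtons vs. a quality index in \[0, 1\]).
#'
#' Training is deterministic under `seed`: the same data and seed give
#' bitwise-identical weights.
#'
#' @param X numeric matrix, samples x predictors.
#' @param y numeric response vector.
#' @param hidden_units number of hidden units (default 8).
#' @param seed integer seed controlling weight initialization.
#' @param maxit epoch cap for the optimizer (default 500).
#' @param decay L2 weight-decay penalty (default 1e-3); a small positive
#'   value regularizes the many-weights spectral problem.
#' @return An `ann_model` holding the layer weight arrays, the per-column
#'   input scaler, the response scaler and the seed.
#' @examples
#' X <- matrix(rnorm(200), 50, 4)
#' y <- X[, 1] * 3 + 1
#' m <- ann_fit(X, y, hidden_units = 4, seed = 1)
#' cor(ann_predict(m, X), y)
#' @export
ann_fit <- function(X, y, hidden_units = 8L, seed = 1L, maxit = 500L,
                    decay = 1e-3) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), hidden_units >= 1)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("ann_fit: X and y must be finite", call. = FALSE)
  }

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale < 1e-12] <- 1   # constant columns carry no information
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")

  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale < 1e-12) {
    # constant response: the exact optimum is the zero network, which
    # predicts y_center everywhere; skip the optimizer
    zero <- list(hidden = matrix(0, ncol(X) + 1, hidden_units),
                 output = numeric(hidden_units + 1))
    return(structure(list(weights = zero,
                          hidden_units = as.integer(hidden_units),
                          activation = "logistic",
                          x_center = x_center, x_scale = x_scale,
                          y_center = y_center, y_scale = 1,
                          seed = as.integer(seed),
                          maxit = as.integer(maxit), decay = decay,
                          final_loss = 0),
                     class = "ann_model"))
  }
  ys <- (y - y_center) / y_scale

  n_wts <- (ncol(X) + 1) * hidden_units + (hidden_units + 1)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  fit <- nnet::nnet(Xs, ys, size = hidden_units, linout = TRUE,
                    maxit = maxit, decay = decay, trace = FALSE,
                    MaxNWts = n_wts + 1)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  if (any(!is.finite(fit$wts)) || !is.finite(fit$value)) {
    stop("ann_fit: training diverged (non-finite loss); final value = ",
         fit$value, ", seed = ", seed, ", decay = ", decay, call. = FALSE)
  }

  structure(list(weights = ann_unpack_weights(fit$wts, ncol(X), hidden_units),
                 hidden_units = as.integer(hidden_units),
                 activation = "logistic",
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 seed = as.integer(seed),
                 maxit = as.integer(maxit), decay = decay,
                 final_loss = fit$value),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("ANN calibration: %d inputs -> %d hidden (logistic) -> 1, seed %d\n",
              length(x$x_center), x$hidden_units, x$seed))
  invisible(x)
}

# nnet packs weights as, per hidden unit, (bias, inputs...), then the
# output unit's (bias, hiddens...). Unpack into explicit layer matrices so
# prediction does not depend on the nnet object (models round-trip through
# JSON bit-exactly).
ann_unpack_weights <- function(wts, n_in, n_hidden) {
  n1 <- (n_in + 1) * n_hidden
  stopifnot(length(wts) == n1 + n_hidden + 1)
  list(hidden = matrix(wts[seq_len(n1)], nrow = n_in + 1),   # (1+in) x hidden
       output = wts[(n1 + 1):length(wts)])                   # 1 + hidden
}

ann_forward <- function(weights, Xs) {
  h <- stats::plogis(cbind(1, Xs) %*% weights$hidden)
  as.numeric(cbind(1, h) %*% weights$output)
}

#' Predict from a fitted ANN calibration
#'
#' @param m an [ann_fit()] model.
#' @param X new predictor matrix with the training column count.
#' @return Numeric vector of predictions on the original response scale.
#' @export
ann_predict <- function(m, X) {
  stopifnot(inherits(m, "ann_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(m$x_center)) {
    stop("ann_predict: X has ", ncol(X), " columns, model expects ",
         length(m$x_center), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, m$x_center), 2, m$x_scale, "/")
  ann_forward(m$weights, Xs) * m$y_scale + m$y_center
}

#' @export
predict.ann_model <- function(object, newdata, ...) ann_predict(object, newdata)
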