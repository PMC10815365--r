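#' Persist a calibration model as JSON
#'
#' Writes a self-describing JSON container (method tag, hyperparameters,
#' centering/scaling vectors, weight arrays, optional metrics block and
#' preprocessing provenance) that [read_calibration_model()] restores to a
#' model whose predictions are bit-identical to the original's.
#'
#' @param model a `plsr_model` or `ann_model`.
#' @param path output file path.
#' @param response name of the response the model predicts.
#' @param metrics optional `calibration_metrics` to embed.
#' @param preprocessing optional list describing the spectra preprocessing
#'   (grid, Savitzky-Golay window/order, absorbance flag) the model expects.
#' @return `path`, invisibly.
#' @export
write_calibration_model <- function(model, path, response = "",
                                    metrics = NULL, preprocessing = NULL) {
  doc <- if (inherits(model, "plsr_model")) {
    list(method = "plsr",
         response = response,
         n_components = model$n_components,
         x_mean = enc_num(model$x_mean), y_mean = enc_num(model$y_mean),
         weights = enc_mat(model$weights),
         x_loadings = enc_mat(model$x_loadings),
         y_loadings = enc_num(model$y_loadings),
         coef_path = enc_mat(model$coef_path))
  } else if (inherits(model, "ann_model")) {
    list(method = "ann",
         response = response,
         hidden_units = model$hidden_units,
         activation = model$activation,
         hidden_weights = enc_mat(model$weights$hidden),
         output_weights = enc_num(model$weights$output),
         x_center = enc_num(model$x_center), x_scale = enc_num(model$x_scale),
         y_center = enc_num(model$y_center), y_scale = enc_num(model$y_scale),
         seed = model$seed, maxit = model$maxit, decay = model$decay)
  } else {
    stop("write_calibration_model: unsupported model class", call. = FALSE)
  }
  if (!is.null(metrics)) {
    doc$metrics <- list(r_squared = metrics$r_squared, rmsec = metrics$rmsec,
                        r_squared_cv = metrics$r_squared_cv,
                        rmsecv = metrics$rmsecv,
                        n_components_or_units = metrics$n_components_or_units,
                        folds = metrics$folds, seed = metrics$seed)
  }
  if (!is.null(preprocessing)) doc$preprocessing <- preprocessing
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- if (doc$method == "plsr") {
    cp <- dec_mat(doc$coef_path)
    structure(list(n_components = as.integer(doc$n_components),
                   requested_components = as.integer(doc$n_components),
                   x_mean = dec_num(doc$x_mean),
                   y_mean = dec_num(doc$y_mean),
                   weights = dec_mat(doc$weights),
                   x_loadings = dec_mat(doc$x_loadings),
                   y_loadings = dec_num(doc$y_loadings),
                   scores = NULL,
                   coef_path = cp,
                   regression_vector = cp[, ncol(cp)]),
              class = "plsr_model")
  } else if (doc$method == "ann") {
    structure(list(weights = list(hidden = dec_mat(doc$hidden_weights),
                                  output = dec_num(doc$output_weights)),
                   hidden_units = as.integer(doc$hidden_units),
                   activation = doc$activation,
                   x_center = dec_num(doc$x_center),
                   x_scale = dec_num(doc$x_scale),
                   y_center = dec_num(doc$y_center),
                   y_scale = dec_num(doc$y_scale),
                   seed = as.integer(doc$seed),
                   maxit = as.integer(doc$maxit), decay = doc$decay,
                   final_loss = NA_real_),
              class = "ann_model")
  } else {
    stop("read_calibration_model: unknown method '", doc$method, "' in ",
         path, call. = FALSE)
  }
  list(model = model, response = doc$response,
       metrics = doc$metrics, preprocessing = doc$preprocessing)
}

# Doubles are stored as C99 hexadecimal float literals ("%a"), the only
# plain-text encoding that round-trips IEEE doubles bit-exactly; decimal
# JSON numbers lose the last couple of bits.
enc_num <- function(x) sprintf("%a", x)
dec_num <- function(x) as.numeric(x)
enc_mat <- function(m) {
  list(nrow = nrow(m), ncol = ncol(m), data = enc_num(as.numeric(m)))
}
dec_mat <- function(l) {
  matrix(as.numeric(unlist(l$data)), as.integer(l$nrow), as.integer(l$ncol))
}

#' Predict with a model of either method
#'
#' @param model a `plsr_model` or `ann_model`.
#' @param X predictor matrix.
#' @return Numeric predictions.
#' @export
calibration_predict <- function(model, X) {
  if (inherits(model, "plsr_model")) plsr_predict(model, X)
  else if (inherits(model, "ann_model")) ann_predict(model, X)
  else stop("calibration_predict: unsupported model class", call. = FALSE)
}
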