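# The source-domain ("base") selectivity model: per-feature scaler fit
# on the full training set, then the chosen regressor on scaled
# features. Prediction target is the free-energy difference in kcal/mol.

#' Fit the source-domain selectivity model
#'
#' @param dataset An [encoded_dataset()] (or list with `x` and `y`).
#' @param spec A [regressor_spec()]; default is the linear support vector
#'   regressor that wins the standard algorithm comparison.
#' @return A `base_model` with the fitted scaler, regressor, training
#'   schema and a training-set fingerprint. For linear algorithms the
#'   model carries explicit weights (see [coef.base_model()]) and is
#'   JSON-serializable via [write_model()].
#' @export
fit_base <- function(dataset, spec = regressor_spec("linear_svr")) {
  x <- dataset$x
  y <- dataset$y
  if (is.null(x) || nrow(x) == 0) stop("empty dataset", call. = FALSE)
  scaler <- if (spec$scaling == "standardize") fit_scaler(x)
            else identity_scaler(ncol(x), colnames(x))
  fit <- fit_regressor(apply_scaler(x, scaler), y, spec)
  fitted <- predict_regressor(fit, apply_scaler(x, scaler))
  structure(list(spec = spec, scaler = scaler, fit = fit,
                 schema = colnames(x), n_train = nrow(x),
                 fitted_values = fitted, y_train = y,
                 fingerprint = content_hash(list(dim(x), sum(x), sum(y)))),
            class = "base_model")
}

#' Predict free-energy differences from a fitted model
#'
#' @param object A `base_model`.
#' @param newdata Encoding matrix (rows = reactions), a single encoding
#'   vector, or an [encoded_dataset()]. Must match the training schema.
#' @param ... Unused.
#' @return Predicted free-energy differences (kcal/mol).
#' @export
predict.base_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "encoded_dataset")) newdata$x else newdata
  x <- as_matrix_row(x)
  check_schema(x, object$schema)
  predict_regressor(object$fit, apply_scaler(x, object$scaler))
}

#' @export
print.base_model <- function(x, ...) {
  cat("<base_model>", x$spec$algorithm, "| n =", x$n_train,
      "| p =", length(x$schema), "| fingerprint", x$fingerprint, "\n")
  invisible(x)
}

#' @export
summary.base_model <- function(object, ...) {
  res <- object$y_train - object$fitted_values
  out <- list(spec = object$spec, n = object$n_train,
              p = length(object$schema),
              train_mae = mae(object$fitted_values, object$y_train),
              train_r = if (stats::sd(object$fitted_values) > 0)
                stats::cor(object$fitted_values, object$y_train) else NA_real_,
              residual_range = range(res))
  class(out) <- "summary.base_model"
  out
}

#' @export
print.summary.base_model <- function(x, ...) {
  cat("Selectivity model (", x$spec$algorithm, ")\n", sep = "")
  cat("  n =", x$n, " features =", x$p, "\n")
  cat("  training MAE:", round(x$train_mae, 4), "kcal/mol | R:",
      round(x$train_r, 3), "\n")
  cat("  residual range:", paste(round(x$residual_range, 3), collapse = " .. "),
      "kcal/mol\n")
  invisible(x)
}

#' Model coefficients on the original descriptor scale
#'
#' For linear regressors, returns the intercept and per-descriptor
#' weights back-transformed through the scaler, so that
#' `pred = b + sum(w * x)` holds on raw encodings.
#'
#' @param object A `base_model`.
#' @param ... Unused.
#' @export
coef.base_model <- function(object, ...) {
  if (object$fit$kind != "linear") {
    stop("coefficients are only available for linear regressors", call. = FALSE)
  }
  w <- object$fit$w / object$scaler$scale
  b <- object$fit$b - sum(object$fit$w * object$scaler$center / object$scaler$scale)
  c(`(Intercept)` = unname(b), w)
}

#' @export
residuals.base_model <- function(object, ...) {
  object$y_train - object$fitted_values
}

#' @export
plot.base_model <- function(x, ...) {
  graphics::plot(x$y_train, x$fitted_values,
                 xlab = expression(paste("experimental ", Delta, Delta, "G (kcal/mol)")),
                 ylab = expression(paste("fitted ", Delta, Delta, "G (kcal/mol)")),
                 main = paste("Base model:", x$spec$algorithm), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
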