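# Delta learning: the base model's residuals on a handful of
# target-reaction measurements (D = ddg_pred - ddg_exp) are themselves
# regressed on the reaction encoding, and the corrected predictor is
# base - D-hat. With the substrate context fixed across the target set,
# only the CCA block (and temperature, if varied) carries information;
# zero-variance columns are dropped before the delta fit and recorded.

#' Default delta-model specification
#'
#' Linear SVR with stronger regularization than the base model
#' (`cost = 0.5`) and a tight epsilon tube (`0.01` kcal/mol): residuals
#' span only a few tenths of a kcal/mol, so the base default epsilon of
#' 0.1 would swallow most of the signal, and with n of order 10 against
#' ~100 features heavier shrinkage is needed.
#'
#' @return A [regressor_spec()].
#' @export
delta_spec_default <- function() regressor_spec("linear_svr", cost = 0.5, epsilon = 0.01)

#' Base-model residuals on the target reaction
#'
#' For every target-domain record, stores the base prediction, the
#' experimental value and their difference `D = ddg_pred - ddg_exp`
#' (kcal/mol) — the training signal for delta learning.
#'
#' @param base A fitted [fit_base()] model.
#' @param target_records Target-domain [reaction_records()].
#' @param tables Descriptor tables (named list: `indole`, `alkene`, `cca`).
#' @return A `delta_records` data frame with columns `cca_id`,
#'   `ddg_pred_base`, `ddg_exp`, `D`, carrying the encoding matrix as an
#'   attribute.
#' @export
compute_residuals <- function(base, target_records, tables) {
  if (nrow(target_records) == 0) stop("no target records", call. = FALSE)
  x <- encode_reactions(target_records, tables)
  pred <- predict(base, x)
  out <- data.frame(cca_id = target_records$cca_id,
                    ddg_pred_base = pred,
                    ddg_exp = target_records$ddg_exp,
                    stringsAsFactors = FALSE)
  out$D <- out$ddg_pred_base - out$ddg_exp
  attr(out, "encoded") <- x
  attr(out, "temperature") <- target_records$temperature
  class(out) <- c("delta_records", "data.frame")
  out
}

# Columns that vary across the delta set; constant columns cannot be
# learned from and would break standardization.
varying_columns <- function(x) {
  apply(x, 2, function(col) stats::sd(col) > 0)
}

#' Fit the delta (residual-correction) model
#'
#' @param delta_records A [compute_residuals()] result (>= 2 rows).
#' @param spec Regressor specification; default [delta_spec_default()].
#' @param orientation `"D"` (default) trains on `D = ddg_pred - ddg_exp`
#'   and the correction is subtracted; `"negD"` trains on `-D` and the
#'   correction is added. Both orientations define the same corrected
#'   predictor `base - D-hat`.
#' @return A `delta_model` with the fitted regressor, the kept-column
#'   set, and the dropped (zero-variance) column names.
#' @export
fit_delta <- function(delta_records, spec = delta_spec_default(),
                      orientation = c("D", "negD")) {
  orientation <- match.arg(orientation)
  x <- attr(delta_records, "encoded")
  if (is.null(x)) stop("delta_records lost their encoding attribute", call. = FALSE)
  if (nrow(delta_records) < 2) stop("need at least 2 delta records", call. = FALSE)
  keep <- varying_columns(x)
  xk <- x[, keep, drop = FALSE]
  target <- if (orientation == "D") delta_records$D else -delta_records$D
  scaler <- if (spec$scaling == "standardize") fit_scaler(xk)
            else identity_scaler(ncol(xk), colnames(xk))
  fit <- fit_regressor(apply_scaler(xk, scaler), target, spec)
  structure(list(spec = spec, orientation = orientation, scaler = scaler,
                 fit = fit, keep = colnames(xk),
                 dropped = colnames(x)[!keep],
                 schema = colnames(x), n_train = nrow(x)),
            class = "delta_model")
}

# Predicted D (always in the subtraction orientation, D = ddg_pred - ddg_exp),
# whatever orientation the regressor was trained in.
predict_D <- function(delta, x) {
  x <- as_matrix_row(x)
  check_schema(x, delta$schema)
  xk <- x[, delta$keep, drop = FALSE]
  raw <- predict_regressor(delta$fit, apply_scaler(xk, delta$scaler))
  if (delta$orientation == "D") raw else -raw
}

#' @export
print.delta_model <- function(x, ...) {
  cat("<delta_model>", x$spec$algorithm, "| n =", x$n_train,
      "| kept", length(x$keep), "of", length(x$schema),
      "columns | orientation", x$orientation, "\n")
  invisible(x)
}

#' Leave-one-out evaluation of delta learning
#'
#' For each target record the delta model is refit on the remaining
#' n - 1 records and the held-out corrected prediction
#' `ddg_pred_base - D-hat` is compared with experiment. Reports the MAE
#' before (`mae_uncorrected`) and after (`mae_corrected`) correction.
#'
#' @param delta_records A [compute_residuals()] result (>= 3 rows).
#' @param spec Regressor specification; default [delta_spec_default()].
#' @return A `loo_report` with `n`, `mae_uncorrected`, `mae_corrected`
#'   (kcal/mol) and a `per_point` data frame.
#' @export
loo_evaluate <- function(delta_records, spec = delta_spec_default()) {
  n <- nrow(delta_records)
  if (n < 3) stop("need at least 3 delta records for leave-one-out", call. = FALSE)
  x <- attr(delta_records, "encoded")
  corrected <- vapply(seq_len(n), function(i) {
    train <- delta_records[-i, , drop = FALSE]
    attr(train, "encoded") <- x[-i, , drop = FALSE]
    class(train) <- class(delta_records)
    dm <- fit_delta(train, spec)
    delta_records$ddg_pred_base[i] - predict_D(dm, x[i, , drop = FALSE])
  }, numeric(1))
  structure(list(
    n = n,
    mae_uncorrected = mae(delta_records$ddg_pred_base, delta_records$ddg_exp),
    mae_corrected = mae(corrected, delta_records$ddg_exp),
    per_point = data.frame(cca_id = delta_records$cca_id,
                           ddg_corrected = corrected,
                           ddg_exp = delta_records$ddg_exp,
                           stringsAsFactors = FALSE)),
    class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat("<loo_report> n =", x$n, "\n")
  cat("  MAE uncorrected:", round(x$mae_uncorrected, 4), "kcal/mol\n")
  cat("  MAE corrected:  ", round(x$mae_corrected, 4), "kcal/mol\n")
  invisible(x)
}
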