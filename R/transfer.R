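# The knowledge-transfer model: source-trained base regressor plus
# residual-trained delta regressor, combined additively. Also the naive
# pooled-training baseline it is compared against.

#' Fit the knowledge-transfer model
#'
#' Computes base-model residuals on the target records, fits the delta
#' regressor, and returns the composite predictor
#' `predict = predict_base - D-hat` (exact additivity by construction).
#'
#' @param base A fitted [fit_base()] model (source domain).
#' @param target_records Target-domain [reaction_records()].
#' @param tables Descriptor tables (named list: `indole`, `alkene`, `cca`).
#' @param spec Delta regressor specification; default [delta_spec_default()].
#' @param convention `"base_minus_D"` (default) or `"base_plus_negD"`;
#'   the two orientations give identical corrected predictions and the
#'   flag records which way the delta regressor was trained.
#' @param loo If `TRUE` (default) a leave-one-out report is attached.
#' @return A `transfer_model`.
#' @export
fit_transfer <- function(base, target_records, tables,
                         spec = delta_spec_default(),
                         convention = c("base_minus_D", "base_plus_negD"),
                         loo = TRUE) {
  convention <- match.arg(convention)
  dr <- compute_residuals(base, target_records, tables)
  delta <- fit_delta(dr, spec,
                     orientation = if (convention == "base_minus_D") "D" else "negD")
  structure(list(base = base, delta = delta, delta_records = dr,
                 convention = convention,
                 loo = if (loo && nrow(dr) >= 3) loo_evaluate(dr, spec) else NULL),
            class = "transfer_model")
}

#' Predict with the knowledge-transfer model
#'
#' @param object A `transfer_model`.
#' @param newdata Encoding matrix / vector or [encoded_dataset()].
#' @param components If `TRUE`, return a data frame with the base
#'   prediction, the predicted residual `D`, and the corrected total
#'   (`total = base - D`, exactly).
#' @param ... Unused.
#' @return Corrected free-energy predictions (kcal/mol), or the
#'   component data frame.
#' @export
predict.transfer_model <- function(object, newdata, components = FALSE, ...) {
  x <- if (inherits(newdata, "encoded_dataset")) newdata$x else newdata
  x <- as_matrix_row(x)
  base <- predict(object$base, x)
  D_hat <- predict_D(object$delta, x)
  if (components) {
    data.frame(ddg_base = base, D_hat = D_hat, ddg_corrected = base - D_hat)
  } else {
    base - D_hat
  }
}

#' @export
print.transfer_model <- function(x, ...) {
  cat("<transfer_model> base:", x$base$spec$algorithm,
      "(n =", paste0(x$base$n_train, ")"),
      "+ delta:", x$delta$spec$algorithm,
      "(n =", paste0(x$delta$n_train, ")"),
      "| convention:", x$convention, "\n")
  if (!is.null(x$loo)) {
    cat("  LOO MAE:", round(x$loo$mae_uncorrected, 3), "->",
        round(x$loo$mae_corrected, 3), "kcal/mol\n")
  }
  invisible(x)
}

#' Naive pooled-training baseline
#'
#' Fits a single regressor on the union of source and target records
#' with no domain indicator — the reparametrized model the transfer
#' approach is contrasted with. With an empty target set this reduces
#' exactly to [fit_base()] on the source data.
#'
#' @param source_records,target_records [reaction_records()] for the two
#'   domains (`target_records` may have zero rows).
#' @param tables Descriptor tables.
#' @param spec Regressor specification (default: base-model default).
#' @return A `base_model` fit on the pooled data.
#' @export
fit_naive_pooled <- function(source_records, target_records, tables,
                             spec = regressor_spec("linear_svr")) {
  if (nrow(source_records) == 0 && nrow(target_records) == 0) {
    stop("empty union of source and target records", call. = FALSE)
  }
  pooled <- rbind(as.data.frame(source_records), as.data.frame(target_records))
  fit_base(encoded_dataset(pooled, tables), spec)
}
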