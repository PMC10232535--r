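# k-fold cross-validation and algorithm ranking. The fold split is a
# seeded random partition (sizes differing by at most one) and is stored
# in the report, since printed CV metrics are only reproducible together
# with their split. Scaling statistics are refit inside every training
# fold: held-out rows never touch the scaler.

make_folds <- function(n, k, seed) {
  if (k > n) stop("k = ", k, " exceeds dataset size n = ", n, call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' k-fold cross-validation of one regressor specification
#'
#' @param dataset An [encoded_dataset()] (or list with `x`, `y`, and
#'   optionally `ids`).
#' @param spec A [regressor_spec()].
#' @param k Fold count (default 10); `k = n` gives leave-one-out.
#' @param seed Seed for the fold shuffle (default 0).
#' @return A `cv_report`: spec, fold assignment, pooled out-of-fold
#'   predictions, `pearson_r` (with `pearson_defined` flag) and `mae` in
#'   kcal/mol.
#' @export
kfold_cv <- function(dataset, spec, k = 10, seed = 0) {
  x <- dataset$x
  y <- dataset$y
  n <- nrow(x)
  ids <- dataset$ids %||% rownames(x) %||% as.character(seq_len(n))
  folds <- make_folds(n, k, seed)
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    train <- folds != f
    scaler <- if (spec$scaling == "standardize") fit_scaler(x[train, , drop = FALSE])
              else identity_scaler(ncol(x), colnames(x))
    fit <- fit_regressor(apply_scaler(x[train, , drop = FALSE], scaler),
                         y[train], spec)
    pred[!train] <- predict_regressor(fit, apply_scaler(x[!train, , drop = FALSE], scaler))
  }
  defined <- stats::sd(y) > 0 && stats::sd(pred) > 0
  r <- if (defined) stats::cor(pred, y) else NA_real_
  structure(list(spec = spec, k = k, seed = seed,
                 per_sample_prediction = stats::setNames(pred, ids),
                 observed = stats::setNames(y, ids),
                 pearson_r = r, pearson_defined = defined,
                 mae = mae(pred, y),
                 fold_assignment = stats::setNames(folds, ids)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$spec$algorithm, "|", x$k, "folds (seed", x$seed, ")\n")
  cat("  Pearson R:", if (x$pearson_defined) round(x$pearson_r, 3) else "undefined",
      "| MAE:", round(x$mae, 4), "kcal/mol\n")
  invisible(x)
}

#' Compare regression algorithms by cross-validation
#'
#' Runs [kfold_cv()] for every specification on the same fold split and
#' orders the reports by descending Pearson R (undefined last), ties
#' broken by ascending MAE, then by input position (stable).
#'
#' @inheritParams kfold_cv
#' @param specs List of [regressor_spec()]s (default:
#'   [default_algorithm_zoo()]).
#' @return List of `cv_report`s, best first.
#' @export
rank_algorithms <- function(dataset, specs = default_algorithm_zoo(),
                            k = 10, seed = 0) {
  if (!length(specs)) stop("need at least one regressor_spec", call. = FALSE)
  reports <- lapply(specs, function(s) kfold_cv(dataset, s, k = k, seed = seed))
  r <- vapply(reports, function(rep) if (rep$pearson_defined) rep$pearson_r else -Inf,
              numeric(1))
  m <- vapply(reports, function(rep) rep$mae, numeric(1))
  reports[order(-r, m, seq_along(reports))]
}
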