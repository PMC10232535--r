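# Ranking metrics for the algorithm comparison: product-moment
# correlation and mean absolute error, both on pooled out-of-fold
# predictions.

#' Pearson correlation with an explicit undefined flag
#'
#' Standard product-moment correlation. A constant input makes the
#' correlation undefined; rather than propagating NaN, `NA` is returned
#' with a warning and downstream reports carry a `pearson_defined` flag.
#'
#' @param a,b Equal-length numeric vectors (length >= 2).
#' @return Correlation in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
pearson_r <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("pearson_r undefined: constant input", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Mean absolute error
#'
#' @param a,b Equal-length numeric vectors; units are preserved.
#' @return `mean(abs(a - b))`.
#' @export
mae <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  mean(abs(a - b))
}
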