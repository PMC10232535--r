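# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream derivation: every stochastic operation inside a
# composite run draws its own seed from (seed, stream id) so that adding a
# stage never shifts the random numbers of another.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) * 131L + stream * 7919L) %% 2147483647L)
}

# Column standardization fit on training rows only. Zero-variance columns
# (e.g. a constant temperature descriptor, or substrate blocks in a
# fixed-context delta set) get unit scale so they map to exactly zero.
fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

identity_scaler <- function(p, names = NULL) {
  list(center = stats::setNames(rep(0, p), names),
       scale = stats::setNames(rep(1, p), names))
}

# Small stable content hash (FNV-1a over a serialized representation);
# used to fingerprint training data and configs in reports.
content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

as_matrix_row <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x
}

check_schema <- function(x, schema) {
  if (ncol(x) != length(schema)) {
    stop("encoding has ", ncol(x), " columns but the model was trained on ",
         length(schema), call. = FALSE)
  }
  if (!is.null(colnames(x)) && !identical(colnames(x), schema)) {
    stop("encoding column names do not match the training schema",
         call. = FALSE)
  }
  invisible(TRUE)
}
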