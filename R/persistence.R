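# Versioned JSON persistence. Linear models are stored exactly (scaler
# statistics + weight vector + intercept + schema); reloaded models
# reproduce predictions bit-for-bit because prediction is the same
# linear-algebra path. Tree/kernel models are not serialized.

MODEL_FORMAT_VERSION <- "1"

serialize_linear <- function(scaler, fit, schema) {
  list(center = unname(scaler$center), scale = unname(scaler$scale),
       w = unname(fit$w), b = fit$b, schema = schema)
}

deserialize_linear <- function(obj) {
  schema <- unlist(obj$schema)
  list(scaler = list(center = stats::setNames(unlist(obj$center), schema),
                     scale = stats::setNames(unlist(obj$scale), schema)),
       fit = list(kind = "linear",
                  w = stats::setNames(unlist(obj$w), schema),
                  b = obj$b))
}

spec_to_list <- function(spec) {
  list(algorithm = spec$algorithm,
       hyperparameters = spec$hyperparameters[
         !vapply(spec$hyperparameters, is.null, logical(1))],
       scaling = spec$scaling)
}

spec_from_list <- function(obj) {
  do.call(regressor_spec,
          c(list(algorithm = obj$algorithm, scaling = obj$scaling),
            obj$hyperparameters))
}

#' Save a fitted model as versioned JSON
#'
#' Supports `base_model` and `transfer_model` objects whose regressors
#' are linear (`linear_svr`, `ridge`, `lasso`); these round-trip with
#' bit-identical predictions. Tree and kernel models raise an error.
#'
#' @param model A `base_model` or `transfer_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "base_model")) {
    if (model$fit$kind != "linear") {
      stop("JSON persistence supports linear regressors only", call. = FALSE)
    }
    obj <- list(format_version = MODEL_FORMAT_VERSION, type = "base_model",
                spec = spec_to_list(model$spec),
                n_train = model$n_train, fingerprint = model$fingerprint,
                linear = serialize_linear(model$scaler, model$fit, model$schema))
  } else if (inherits(model, "transfer_model")) {
    if (model$base$fit$kind != "linear" || model$delta$fit$kind != "linear") {
      stop("JSON persistence supports linear regressors only", call. = FALSE)
    }
    obj <- list(format_version = MODEL_FORMAT_VERSION, type = "transfer_model",
                convention = model$convention,
                base = list(spec = spec_to_list(model$base$spec),
                            n_train = model$base$n_train,
                            fingerprint = model$base$fingerprint,
                            linear = serialize_linear(model$base$scaler,
                                                      model$base$fit,
                                                      model$base$schema)),
                delta = list(spec = spec_to_list(model$delta$spec),
                             orientation = model$delta$orientation,
                             n_train = model$delta$n_train,
                             keep = model$delta$keep,
                             dropped = model$delta$dropped,
                             schema = model$delta$schema,
                             linear = serialize_linear(model$delta$scaler,
                                                       model$delta$fit,
                                                       model$delta$keep)))
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  # digits = I(17): decimal-lossless doubles, so reloaded models predict
  # bit-identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Load a model saved by [write_model()]
#'
#' @param path Path to a model JSON file.
#' @return A `base_model` or `transfer_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    stop("unsupported model format version: ", obj$format_version, call. = FALSE)
  }
  if (identical(obj$type, "base_model")) {
    lin <- deserialize_linear(obj$linear)
    structure(list(spec = spec_from_list(obj$spec), scaler = lin$scaler,
                   fit = lin$fit, schema = unlist(obj$linear$schema),
                   n_train = obj$n_train, fitted_values = NULL, y_train = NULL,
                   fingerprint = obj$fingerprint),
              class = "base_model")
  } else if (identical(obj$type, "transfer_model")) {
    bl <- deserialize_linear(obj$base$linear)
    base <- structure(list(spec = spec_from_list(obj$base$spec),
                           scaler = bl$scaler, fit = bl$fit,
                           schema = unlist(obj$base$linear$schema),
                           n_train = obj$base$n_train,
                           fitted_values = NULL, y_train = NULL,
                           fingerprint = obj$base$fingerprint),
                      class = "base_model")
    dl <- deserialize_linear(obj$delta$linear)
    delta <- structure(list(spec = spec_from_list(obj$delta$spec),
                            orientation = obj$delta$orientation,
                            scaler = dl$scaler, fit = dl$fit,
                            keep = unlist(obj$delta$keep),
                            dropped = as.character(unlist(obj$delta$dropped)),
                            schema = unlist(obj$delta$schema),
                            n_train = obj$delta$n_train),
                       class = "delta_model")
    structure(list(base = base, delta = delta, delta_records = NULL,
                   convention = obj$convention, loo = NULL),
              class = "transfer_model")
  } else {
    stop("unknown model type in ", path, call. = FALSE)
  }
}
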