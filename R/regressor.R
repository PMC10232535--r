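# Regressor zoo. The contribution of this package is the transfer
# workflow, not the learners: every algorithm here is a thin, seeded
# wrapper around an established implementation (e1071, glmnet,
# randomForest, xgboost, caret), fit on features standardized by the
# caller. Linear learners are reduced to an explicit (w, b) pair so that
# prediction, persistence and coefficient inspection are exact.

ALGORITHMS <- c("linear_svr", "ridge", "lasso", "kernel_svr",
                "random_forest", "gradient_boosting", "k_neighbors")

HYPER_DEFAULTS <- list(
  linear_svr        = list(cost = 1, epsilon = 0.1),
  ridge             = list(lambda = 0.1),
  lasso             = list(lambda = 0.05),
  kernel_svr        = list(cost = 1, epsilon = 0.1, gamma = NULL),
  random_forest     = list(ntree = 500, mtry = NULL, seed = 0),
  gradient_boosting = list(nrounds = 200, eta = 0.1, max_depth = 3, seed = 0),
  k_neighbors       = list(k = 5)
)

#' Specify a regression algorithm
#'
#' @param algorithm One of `"linear_svr"`, `"ridge"`, `"lasso"`,
#'   `"kernel_svr"`, `"random_forest"`, `"gradient_boosting"`,
#'   `"k_neighbors"`.
#' @param ... Hyperparameter overrides; names are validated against the
#'   chosen algorithm (`linear_svr`: `cost`, `epsilon`; `ridge`/`lasso`:
#'   `lambda`; `kernel_svr`: `cost`, `epsilon`, `gamma`; `random_forest`:
#'   `ntree`, `mtry`, `seed`; `gradient_boosting`: `nrounds`, `eta`,
#'   `max_depth`, `seed`; `k_neighbors`: `k`).
#' @param scaling `"standardize"` (default; per-feature centring/scaling
#'   fit on training rows only, zero-variance guarded) or `"none"`.
#' @return A `regressor_spec`.
#' @export
regressor_spec <- function(algorithm = ALGORITHMS, ...,
                           scaling = c("standardize", "none")) {
  algorithm <- match.arg(algorithm)
  scaling <- match.arg(scaling)
  defaults <- HYPER_DEFAULTS[[algorithm]]
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameter(s) for ", algorithm, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hyper <- utils::modifyList(defaults, override)
  structure(list(algorithm = algorithm, hyperparameters = hyper,
                 scaling = scaling),
            class = "regressor_spec")
}

#' @export
print.regressor_spec <- function(x, ...) {
  hp <- x$hyperparameters
  hp <- hp[!vapply(hp, is.null, logical(1))]
  cat("<regressor_spec>", x$algorithm, "(",
      paste(names(hp), unlist(hp), sep = "=", collapse = ", "),
      ") scaling:", x$scaling, "\n")
  invisible(x)
}

#' The default algorithm comparison set
#'
#' Seven conventional regressors spanning linear, kernel, ensemble and
#' instance-based families, each at library-default-style settings; used
#' by [rank_algorithms()] when no explicit list is given.
#'
#' @return Named list of [regressor_spec()]s.
#' @export
default_algorithm_zoo <- function() {
  specs <- lapply(ALGORITHMS, regressor_spec)
  names(specs) <- ALGORITHMS
  specs
}

need_pkg <- function(pkg, algorithm) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("algorithm '", algorithm, "' needs package '", pkg, "'", call. = FALSE)
  }
}

# Fit one regressor on already-scaled features. Returns either
# kind = "linear" (explicit weights; exact linear prediction path) or
# kind = "object" (opaque fitted object + its predict wrapper).
fit_regressor <- function(xs, y, spec) {
  hp <- spec$hyperparameters
  if (stats::sd(y) == 0) {
    # degenerate constant target: every learner reduces to the constant;
    # e1071's SVR cannot represent it (no support vectors)
    return(list(kind = "linear",
                w = stats::setNames(rep(0, ncol(xs)), colnames(xs)),
                b = y[1]))
  }
  switch(spec$algorithm,
    linear_svr = {
      # an epsilon tube wide enough to hold every centred target leaves no
      # support vectors; the SVR solution is then the constant mean(y)
      fit <- tryCatch(
        e1071::svm(xs, y, type = "eps-regression", kernel = "linear",
                   cost = hp$cost, epsilon = hp$epsilon, scale = FALSE),
        error = function(e) {
          if (grepl("empty", conditionMessage(e))) NULL else stop(e)
        })
      if (is.null(fit) || nrow(fit$SV) == 0) {
        list(kind = "linear",
             w = stats::setNames(rep(0, ncol(xs)), colnames(xs)), b = mean(y))
      } else {
        list(kind = "linear",
             w = stats::setNames(drop(t(fit$coefs) %*% fit$SV), colnames(xs)),
             b = -fit$rho)
      }
    },
    ridge = ,
    lasso = {
      alpha <- if (spec$algorithm == "lasso") 1 else 0
      fit <- glmnet::glmnet(xs, y, alpha = alpha, lambda = hp$lambda,
                            standardize = FALSE)
      beta <- as.numeric(stats::coef(fit))
      list(kind = "linear",
           w = stats::setNames(beta[-1], colnames(xs)), b = beta[1])
    },
    kernel_svr = {
      fit <- tryCatch(
        e1071::svm(xs, y, type = "eps-regression", kernel = "radial",
                   cost = hp$cost, epsilon = hp$epsilon,
                   gamma = hp$gamma %||% (1 / ncol(xs)), scale = FALSE),
        error = function(e) {
          if (grepl("empty", conditionMessage(e))) NULL else stop(e)
        })
      if (is.null(fit) || nrow(fit$SV) == 0) {
        list(kind = "linear",
             w = stats::setNames(rep(0, ncol(xs)), colnames(xs)), b = mean(y))
      } else {
        list(kind = "object", model = fit,
             fun = function(m, newx) as.numeric(stats::predict(m, newx)))
      }
    },
    random_forest = {
      need_pkg("randomForest", spec$algorithm)
      set.seed(hp$seed)
      fit <- randomForest::randomForest(
        xs, y, ntree = hp$ntree,
        mtry = hp$mtry %||% max(1, floor(ncol(xs) / 3)))
      list(kind = "object", model = fit,
           fun = function(m, newx) as.numeric(stats::predict(m, newx)))
    },
    gradient_boosting = {
      need_pkg("xgboost", spec$algorithm)
      set.seed(hp$seed)
      fit <- xgboost::xgboost(
        x = xs, y = y, nrounds = hp$nrounds, learning_rate = hp$eta,
        max_depth = hp$max_depth, nthreads = 1, verbosity = 0,
        objective = "reg:squarederror")
      list(kind = "object", model = fit,
           fun = function(m, newx) as.numeric(stats::predict(m, newx)))
    },
    k_neighbors = {
      need_pkg("caret", spec$algorithm)
      fit <- caret::knnreg(xs, y, k = min(hp$k, nrow(xs)))
      list(kind = "object", model = fit,
           fun = function(m, newx) as.numeric(stats::predict(m, newx)))
    }
  )
}

predict_regressor <- function(fit, xs) {
  if (fit$kind == "linear") {
    unname(drop(xs %*% fit$w)) + fit$b
  } else {
    fit$fun(fit$model, xs)
  }
}
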