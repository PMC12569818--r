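# Regression model registry and fitting.

#' Register a regression model
#'
#' The model registry maps a short name to a fit/predict implementation
#' plus default hyperparameters, so experiment configurations can name
#' models symbolically and new architectures can be plugged in without
#' touching the harness. `fit(x, y, hyperparams, seed)` must return an
#' object that `predict_fn(fit, newx)` maps to a numeric vector, and must
#' be deterministic given `seed`.
#'
#' Built-in models:
#' * `rf` — random forest regression (ranger); hyperparameters
#'   `num.trees` (500), `mtry` (sqrt(p)), `min.node.size` (5).
#' * `svr` — epsilon support vector regression with RBF kernel (e1071);
#'   `cost` (1), `epsilon` (0.1), `gamma` (1/p), `kernel` ("radial").
#' * `ffnn` — single-hidden-layer feed-forward network with linear output
#'   (nnet); `size` (16), `decay` (1e-3), `maxit` (200).
#'
#' @param name Registry key.
#' @param fit Function `(x, y, hyperparams, seed) -> fitted object`.
#' @param predict_fn Function `(fitted, newx) -> numeric`.
#' @param default_hyperparams Named list of defaults; user-supplied
#'   hyperparameters are validated against these names.
#' @param overwrite Allow replacing an existing entry.
#' @return The registry key, invisibly.
#' @export
register_regressor <- function(name, fit, predict_fn,
                               default_hyperparams = list(),
                               overwrite = FALSE) {
  if (!overwrite && name %in% ls(.ddg_registry)) {
    stop_ddg("model '", name, "' is already registered.")
  }
  assign(name, list(fit = fit, predict = predict_fn,
                    defaults = default_hyperparams), envir = .ddg_registry)
  invisible(name)
}

#' @describeIn register_regressor Names of all registered models.
#' @export
list_regressors <- function() sort(ls(.ddg_registry))

register_builtin_regressors <- function() {
  register_regressor(
    "rf",
    fit = function(x, y, hp, seed) {
      colnames(x) <- paste0("f", seq_len(ncol(x)))
      ranger::ranger(
        x = x, y = y,
        num.trees = hp$num.trees, mtry = hp$mtry,
        min.node.size = hp$min.node.size,
        seed = seed, num.threads = 1
      )
    },
    predict_fn = function(fit, newx) {
      colnames(newx) <- paste0("f", seq_len(ncol(newx)))
      predict(fit, newx, num.threads = 1)$predictions
    },
    default_hyperparams = list(num.trees = 500L, mtry = NULL,
                               min.node.size = 5L),
    overwrite = TRUE
  )
  register_regressor(
    "svr",
    fit = function(x, y, hp, seed) {
      e1071::svm(x = x, y = y, type = "eps-regression", kernel = hp$kernel,
                 cost = hp$cost, epsilon = hp$epsilon,
                 gamma = hp$gamma %||% (1 / ncol(x)), scale = FALSE)
    },
    predict_fn = function(fit, newx) as.numeric(predict(fit, newx)),
    default_hyperparams = list(cost = 1, epsilon = 0.1, gamma = NULL,
                               kernel = "radial"),
    overwrite = TRUE
  )
  register_regressor(
    "ffnn",
    fit = function(x, y, hp, seed) {
      with_local_seed(seed, {
        nnet::nnet(x = x, y = y, size = hp$size, decay = hp$decay,
                   maxit = hp$maxit, linout = TRUE, trace = FALSE,
                   MaxNWts = (ncol(x) + 2L) * hp$size + hp$size + 1L + 1000L)
      })
    },
    predict_fn = function(fit, newx) as.numeric(predict(fit, newx)),
    default_hyperparams = list(size = 16L, decay = 1e-3, maxit = 200L),
    overwrite = TRUE
  )
}

#' Fit a ddG regression model
#'
#' Trains a registered model on the feature matrix column of a featurized
#' tibble (single records) or a pair tibble (pairwise dddG targets).
#' Training is deterministic given `seed`.
#'
#' @param data A tibble with a matrix feature column (`feature` or
#'   `pair_feature`, auto-detected) and a numeric target column.
#' @param target Name of the target column; defaults to `target_dddg` for
#'   pair tibbles and `ddg` otherwise.
#' @param model Registry name, see [register_regressor()].
#' @param hyperparams Named list overriding the model's defaults; unknown
#'   names are an error.
#' @param seed Integer seed controlling any training randomness.
#' @return An object of class `ddg_model` with a [predict()][predict.ddg_model]
#'   method; [tidy()] lists the hyperparameters, [glance()] the fit summary.
#' @export
fit_ddg_model <- function(data, target = NULL, model = "rf",
                          hyperparams = list(), seed = 1L) {
  spec <- get_regressor(model)
  feature_col <- if ("pair_feature" %in% names(data)) "pair_feature" else "feature"
  X <- feature_matrix(data, feature_col)
  if (is.null(target)) {
    target <- if (feature_col == "pair_feature") "target_dddg" else "ddg"
  }
  if (!target %in% names(data)) stop_ddg("target column `", target, "` not found.")
  y <- data[[target]]
  if (nrow(X) < 2L) stop_ddg("need at least 2 training rows.")
  if (any(!is.finite(X))) stop_ddg("non-finite values in the feature matrix.")
  if (any(!is.finite(y))) stop_ddg("non-finite values in the target.")

  unknown <- setdiff(names(hyperparams), names(spec$defaults))
  if (length(unknown)) {
    stop_ddg("unknown hyperparameter(s) for '", model, "': ",
             paste(unknown, collapse = ", "), " (valid: ",
             paste(names(spec$defaults), collapse = ", "), ")")
  }
  hp <- modifyList(spec$defaults, hyperparams)
  fit <- spec$fit(X, y, hp, as.integer(seed))
  structure(
    list(model = model, fit = fit, hyperparams = hp, seed = as.integer(seed),
         n = nrow(X), p = ncol(X), feature_col = feature_col,
         target_col = target),
    class = "ddg_model"
  )
}

get_regressor <- function(model) {
  if (!model %in% ls(.ddg_registry)) {
    stop_ddg("unknown model '", model, "'; registered models: ",
             paste(list_regressors(), collapse = ", "))
  }
  get(model, envir = .ddg_registry)
}

#' Predict from a fitted ddG model
#'
#' @param object A `ddg_model`.
#' @param newdata A tibble with the same feature column the model was
#'   trained on, or a bare numeric matrix.
#' @param ... Unused.
#' @return Numeric vector of predictions (ddG or dddG, kcal/mol, depending
#'   on the training target).
#' @export
predict.ddg_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata, object$feature_col)
  if (ncol(X) != object$p) {
    stop_ddg("feature dimension mismatch: model expects ", object$p,
             ", got ", ncol(X))
  }
  spec <- get_regressor(object$model)
  as.numeric(spec$predict(object$fit, X))
}

#' @export
print.ddg_model <- function(x, ...) {
  cat("<ddg_model> ", x$model, ": n = ", x$n, ", p = ", x$p,
      ", target = ", x$target_col, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @method tidy ddg_model
#' @export
tidy.ddg_model <- function(x, ...) {
  hp <- x$hyperparams
  tibble(
    hyperparameter = names(hp),
    value = vapply(hp, function(v) if (is.null(v)) NA_character_ else
      paste(format(v), collapse = ","), character(1))
  )
}

#' @method glance ddg_model
#' @export
glance.ddg_model <- function(x, ...) {
  tibble(model = x$model, n = x$n, p = x$p, target = x$target_col,
         seed = x$seed)
}
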