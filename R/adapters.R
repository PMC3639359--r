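# Learner adapter contract: point-prediction regressors are consumed through
# a registry of fit/predict closures so that the framework never depends on
# the internals of any particular algorithm.

.adapters <- new.env(parent = emptyenv())

#' Register a regression-learner adapter
#'
#' An adapter is a pair of functions: `fit(X, y, params)` returning an
#' opaque fit object, and `predict(fit, X)` returning a numeric vector.
#'
#' @param name algorithm name used in [regressor_spec()].
#' @param fit,predict adapter functions.
#' @return Invisibly, `name`.
#' @export
register_adapter <- function(name, fit, predict) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(fit), is.function(predict))
  assign(name, list(fit = fit, predict = predict), envir = .adapters)
  invisible(name)
}

#' List registered learner adapters
#' @return Character vector of algorithm names.
#' @export
list_adapters <- function() sort(ls(.adapters))

get_adapter <- function(name) {
  if (!exists(name, envir = .adapters, inherits = FALSE)) {
    stop(sprintf("unknown algorithm '%s'; registered: %s", name,
                 paste(list_adapters(), collapse = ", ")), call. = FALSE)
  }
  get(name, envir = .adapters, inherits = FALSE)
}

#' Specify a point-prediction regressor
#'
#' @param algorithm registered adapter name (see [list_adapters()]). Built-in
#'   learners: `"mean"` (constant baseline), `"ridge"` (L2-penalised linear
#'   regression), `"knn"` (distance-weighted k-nearest-neighbour with a
#'   triangular kernel). Adapters for `"rf"` (randomForest, 250 trees,
#'   nodesize 1) and `"svm"` (e1071 radial-kernel SVM, cost 2) are registered
#'   when those packages are available.
#' @param params named list of fixed hyperparameters passed to the adapter.
#' @param tune named list of candidate values per hyperparameter; when
#'   non-empty, [fit_regressor()] and the inner loop of [double_loop_cv()]
#'   pick the combination minimising k-fold cross-validated RMSE using only
#'   the data they are given.
#' @return A `regressor_spec`.
#' @export
regressor_spec <- function(algorithm, params = list(), tune = list()) {
  get_adapter(algorithm) # fail early on unknown algorithms
  structure(list(algorithm = algorithm, params = params, tune = tune),
            class = "regressor_spec")
}

#' @export
print.regressor_spec <- function(x, ...) {
  cat("<regressor_spec>", x$algorithm, "\n")
  if (length(x$params)) cat("  params:", deparse(x$params), "\n")
  if (length(x$tune)) cat("  tune:", deparse(x$tune), "\n")
  invisible(x)
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must align with y", call. = FALSE)
  if (any(!is.finite(X))) stop("X contains missing/non-finite values", call. = FALSE)
  if (any(!is.finite(y))) stop("y contains missing/non-finite values", call. = FALSE)
  X
}

# Grid tuning by k-fold CV RMSE; returns the spec with tuned params fixed.
tune_spec <- function(spec, X, y, folds = 7L, seed = NULL) {
  if (!length(spec$tune)) return(spec)
  grid <- expand.grid(spec$tune, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  folds <- min(folds, nrow(X))
  assign_f <- with_seed(seed, fold_assignment(nrow(X), folds))
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    params <- utils::modifyList(spec$params, as.list(grid[g, , drop = FALSE]))
    errs <- unlist(lapply(seq_len(folds), function(f) {
      tr <- assign_f != f
      ad <- get_adapter(spec$algorithm)
      fit <- ad$fit(X[tr, , drop = FALSE], y[tr], params)
      ad$predict(fit, X[!tr, , drop = FALSE]) - y[!tr]
    }))
    rmse(errs)
  }, numeric(1))
  best <- which.min(scores)
  spec$params <- utils::modifyList(spec$params, as.list(grid[best, , drop = FALSE]))
  spec$tune <- list()
  spec
}

#' Fit a point-prediction model
#'
#' Dispatches to the registered adapter; hyperparameters listed in the
#' spec's `tune` slot are first selected by `inner_folds`-fold
#' cross-validation on the supplied training data only.
#'
#' @param spec a [regressor_spec()].
#' @param X descriptor matrix (rows = compounds).
#' @param y numeric response aligned with the rows of `X`.
#' @param inner_folds folds for hyperparameter tuning (default 7).
#' @param seed optional integer controlling fold assignment and any
#'   stochastic learner; identical seed and data give identical predictions.
#' @return A `qsar_model` supporting `predict(model, newdata)`.
#' @export
fit_regressor <- function(spec, X, y, inner_folds = 7L, seed = NULL) {
  stopifnot(inherits(spec, "regressor_spec"))
  X <- check_xy(X, y)
  if (sd(y) == 0) warning("constant response y; model will predict a constant")
  spec <- tune_spec(spec, X, y, folds = inner_folds, seed = stage_seed(seed, "tune"))
  ad <- get_adapter(spec$algorithm)
  fit <- with_seed(seed, ad$fit(X, y, spec$params))
  structure(list(algorithm = spec$algorithm, params = spec$params, fit = fit),
            class = "qsar_model")
}

#' @export
predict.qsar_model <- function(object, newdata, ...) {
  newdata <- as_matrix_rows(newdata)
  as.numeric(get_adapter(object$algorithm)$predict(object$fit, newdata))
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("<qsar_model>", x$algorithm, "\n")
  invisible(x)
}

#' Fit a bagged ensemble of regressors
#'
#' Trains `n_members` copies of the learner on with-replacement bootstrap
#' resamples of the training rows (each the size of the training set). The
#' ensemble prediction is the member mean; the member spread at a query is
#' the bagged-variance reliability index (see [bagged_variance_score()]).
#' Hyperparameters are tuned once on the full training data and then held
#' fixed across members.
#'
#' @inheritParams fit_regressor
#' @param n_members ensemble size, at least 2 (default 100).
#' @return A `bagged_ensemble`.
#' @export
fit_bagged <- function(spec, X, y, n_members = 100L, seed = NULL,
                       inner_folds = 7L) {
  stopifnot(inherits(spec, "regressor_spec"))
  if (n_members < 2L) stop("`n_members` must be >= 2 (spread undefined)", call. = FALSE)
  X <- check_xy(X, y)
  spec <- tune_spec(spec, X, y, folds = inner_folds, seed = stage_seed(seed, "tune"))
  ad <- get_adapter(spec$algorithm)
  n <- nrow(X)
  members <- with_seed(seed, lapply(seq_len(n_members), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    list(idx = idx, fit = ad$fit(X[idx, , drop = FALSE], y[idx], spec$params))
  }))
  structure(list(algorithm = spec$algorithm, params = spec$params,
                 members = members),
            class = "bagged_ensemble")
}

member_predictions <- function(ensemble, X) {
  X <- as_matrix_rows(X)
  ad <- get_adapter(ensemble$algorithm)
  vapply(ensemble$members, function(m) as.numeric(ad$predict(m$fit, X)),
         numeric(nrow(X)))
}

#' @export
predict.bagged_ensemble <- function(object, newdata, ...) {
  P <- member_predictions(object, newdata)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  rowMeans(P)
}

#' @export
print.bagged_ensemble <- function(x, ...) {
  cat("<bagged_ensemble>", x$algorithm, "with", length(x$members), "members\n")
  invisible(x)
}

#' Double-loop cross-validation
#'
#' Outer folds provide out-of-fold predictions for every training compound;
#' hyperparameter tuning runs inside each outer-training partition with
#' `inner_folds`-fold CV, so the generalisation-error estimate is not biased
#' by the parameterisation of the model. The RMSE of the returned residuals
#' is the CV estimate of the model's forward prediction error.
#'
#' @inheritParams fit_regressor
#' @param outer_folds number of outer folds (>= 2; default 7).
#' @param inner_folds folds for the inner tuning loop (default 7).
#' @return A `cv_table` data frame with one row per training compound:
#'   `index`, `fold`, `observed`, `prediction`, `residual`
#'   (observed - prediction) and `abs_error`.
#' @export
double_loop_cv <- function(spec, X, y, outer_folds = 7L, inner_folds = 7L,
                           seed = NULL) {
  stopifnot(inherits(spec, "regressor_spec"))
  X <- check_xy(X, y)
  if (outer_folds < 2L) stop("`outer_folds` must be >= 2", call. = FALSE)
  n <- nrow(X)
  assign_f <- with_seed(stage_seed(seed, "outer"), fold_assignment(n, outer_folds))
  pred <- numeric(n)
  for (f in seq_len(outer_folds)) {
    tr <- assign_f != f
    if (sum(!tr) < 1L) stop("empty outer fold", call. = FALSE)
    model <- fit_regressor(spec, X[tr, , drop = FALSE], y[tr],
                           inner_folds = inner_folds,
                           seed = stage_seed(seed, paste0("fold", f)))
    pred[!tr] <- predict(model, X[!tr, , drop = FALSE])
  }
  out <- data.frame(index = seq_len(n), fold = assign_f, observed = y,
                    prediction = pred, residual = y - pred,
                    abs_error = abs(y - pred))
  class(out) <- c("cv_table", class(out))
  out
}

# ---- built-in learners ------------------------------------------------------
# Registered from .onLoad so the registry is rebuilt in every session.

register_builtin_adapters <- function() {

register_adapter(
  "mean",
  fit = function(X, y, params) list(mu = mean(y)),
  predict = function(fit, X) rep(fit$mu, nrow(X))
)

register_adapter(
  "ridge",
  fit = function(X, y, params) {
    lambda <- params$lambda %||% 1
    xc <- colMeans(X)
    Xc <- sweep(X, 2L, xc)
    p <- ncol(X)
    beta <- solve(crossprod(Xc) + diag(lambda, p), crossprod(Xc, y - mean(y)))
    list(beta = beta, xc = xc, yc = mean(y))
  },
  predict = function(fit, X) {
    drop(sweep(X, 2L, fit$xc) %*% fit$beta) + fit$yc
  }
)

# Distance-weighted k-NN with a triangular kernel: weights decay linearly
# from 1 at distance zero to 0 at the (k+1)-th neighbour distance. When all
# k distances are zero the neighbours are averaged uniformly.
register_adapter(
  "knn",
  fit = function(X, y, params) {
    list(X = X, y = y, k = params$k %||% 5L,
         kernel = params$kernel %||% "triangular")
  },
  predict = function(fit, X) {
    k <- min(fit$k, nrow(fit$X))
    D <- euclidean_cross_distances(X, fit$X)
    apply_rows_knn(D, function(d, ord) {
      nn <- ord[seq_len(k)]
      dn <- d[nn]
      if (fit$kernel == "triangular") {
        bw <- if (length(ord) > k) d[ord[k + 1L]] else max(dn) + 1e-12
        w <- pmax(1 - dn / max(bw, 1e-12), 0)
        if (sum(w) == 0) w <- rep(1, k)
      } else {
        w <- rep(1, k)
      }
      sum(w * fit$y[nn]) / sum(w)
    })
  }
)

# Optional heavyweight learners, registered only when their packages are
# installed; the framework itself never depends on their internals.
if (requireNamespace("randomForest", quietly = TRUE)) {
  register_adapter(
    "rf",
    fit = function(X, y, params) {
      randomForest::randomForest(
        x = X, y = y,
        ntree = params$ntree %||% 250L,
        nodesize = params$nodesize %||% 1L,
        mtry = params$mtry %||% max(floor(ncol(X) / 3), 1L))
    },
    predict = function(fit, X) predict(fit, X)
  )
}
if (requireNamespace("e1071", quietly = TRUE)) {
  register_adapter(
    "svm",
    fit = function(X, y, params) {
      e1071::svm(x = X, y = y, kernel = "radial",
                 gamma = params$gamma %||% 2^-7,
                 cost = params$cost %||% 2, scale = FALSE)
    },
    predict = function(fit, X) predict(fit, X)
  )
}

invisible(NULL)
}

apply_rows_knn <- function(D, f) {
  vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, ]
    f(d, order(d)) # order() is stable: ties break by ascending row index
  }, numeric(1))
}

# ---- descriptor preprocessing ----------------------------------------------

#' Standardise descriptors with training-set statistics
#'
#' Centres and scales each descriptor to zero mean / unit variance using the
#' training rows, dropping zero-variance descriptors. The same transform is
#' applied to training data, query compounds and all distance computations.
#'
#' @param X training descriptor matrix.
#' @return A `descriptor_scaler`.
#' @export
descriptor_scaler <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  keep <- which(s > 0)
  if (!length(keep)) stop("all descriptors have zero variance", call. = FALSE)
  structure(list(center = mu[keep], scale = s[keep], keep = keep,
                 p_in = ncol(X)),
            class = "descriptor_scaler")
}

#' @rdname descriptor_scaler
#' @param scaler a `descriptor_scaler`.
#' @param newdata matrix (or single row) with the original descriptor layout.
#' @return The standardised matrix restricted to the retained descriptors.
#' @export
apply_scaler <- function(scaler, newdata) {
  stopifnot(inherits(scaler, "descriptor_scaler"))
  newdata <- as_matrix_rows(newdata)
  if (ncol(newdata) != scaler$p_in) {
    stop("descriptor count does not match the scaler", call. = FALSE)
  }
  X <- newdata[, scaler$keep, drop = FALSE]
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")
}
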