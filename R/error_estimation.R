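# Reliability indices (distance-to-model, local error, bagged variance) and
# their conversion into per-compound prediction errors (sigma_pred).

#' Euclidean distance between descriptor vectors
#'
#' `D_EUC(A, B) = sqrt((A - B)(A - B)^T)` on the (standardised) descriptor
#' space.
#'
#' @param a,b numeric vectors of equal length.
#' @return A single nonnegative number.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  sqrt(sum((a - b)^2))
}

# All pairwise Euclidean distances between the rows of Q and the rows of X.
euclidean_cross_distances <- function(Q, X) {
  Q <- as_matrix_rows(Q); X <- as.matrix(X)
  d2 <- outer(rowSums(Q^2), rowSums(X^2), "+") - 2 * tcrossprod(Q, X)
  sqrt(pmax(d2, 0))
}

#' Moore-Penrose pseudo-inverse via singular value decomposition
#'
#' Inverts singular values above `rtol * max(singular values)` and zeroes the
#' rest, so rank-deficient covariance matrices (collinear descriptors) are
#' handled without error.
#'
#' @param M a numeric matrix.
#' @param rtol relative singular-value cutoff.
#' @return The pseudo-inverse matrix.
#' @export
pseudo_inverse <- function(M, rtol = 1e-8) {
  s <- svd(M)
  pos <- s$d > rtol * max(s$d)
  dinv <- ifelse(pos, 1 / s$d, 0)
  s$v %*% (dinv * t(s$u))
}

# Whitening factor W with S_pinv = W W', so Mahalanobis distance reduces to
# Euclidean distance in the transformed coordinates.
mahalanobis_whitener <- function(train_X, rtol = 1e-8) {
  S <- cov(as.matrix(train_X))
  e <- eigen(pseudo_inverse(S, rtol), symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values))
}

#' Mahalanobis distance with an SVD pseudo-inverse covariance
#'
#' `D_MAL(A, B) = sqrt((A - B) S^- (A - B)^T)` where `S^-` is the
#' pseudo-inverse of the training-data covariance matrix, computed by
#' singular value decomposition so that rank-deficient descriptor matrices
#' still yield a finite distance.
#'
#' @param a,b numeric descriptor vectors of equal length.
#' @param train_X training descriptor matrix (>= 2 rows) from which the
#'   covariance is estimated; ignored when `S_pinv` is supplied.
#' @param S_pinv optional precomputed pseudo-inverse covariance.
#' @return A single nonnegative number.
#' @export
mahalanobis_distance <- function(a, b, train_X = NULL, S_pinv = NULL) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (is.null(S_pinv)) {
    if (is.null(train_X) || nrow(as.matrix(train_X)) < 2L) {
      stop("need `train_X` with >= 2 rows (or a precomputed S_pinv)", call. = FALSE)
    }
    S_pinv <- pseudo_inverse(cov(as.matrix(train_X)))
  }
  d <- a - b
  sqrt(max(drop(d %*% S_pinv %*% d), 0))
}

# Query-by-training distance matrix in the requested metric. For the
# Mahalanobis metric both sides are whitened once, which makes k-NN searches
# a plain Euclidean problem.
cross_distances <- function(Q, X, metric = c("euclidean", "mahalanobis"),
                            whitener = NULL) {
  metric <- match.arg(metric)
  if (metric == "mahalanobis") {
    W <- whitener %||% mahalanobis_whitener(X)
    Q <- as_matrix_rows(Q) %*% W
    X <- as.matrix(X) %*% W
  }
  euclidean_cross_distances(Q, X)
}

#' Mean distance to the k nearest training compounds (distance-to-model)
#'
#' The distance-to-model (D2M) reliability index: the average distance of a
#' query compound to its `k` nearest training-set neighbours. Ties are broken
#' deterministically by ascending training-row index.
#'
#' @param x query descriptor vector, or a matrix of query rows.
#' @param train_X training descriptor matrix (same standardisation as `x`).
#' @param k neighbour count, `1 <= k <= nrow(train_X)`.
#' @param metric `"euclidean"` or `"mahalanobis"`.
#' @param whitener optional precomputed whitening factor for the Mahalanobis
#'   metric (see internals); recomputed from `train_X` when absent.
#' @return Numeric vector of mean neighbour distances, one per query row.
#' @export
knn_mean_distance <- function(x, train_X, k, metric = "euclidean",
                              whitener = NULL) {
  train_X <- as.matrix(train_X)
  if (k < 1L || k > nrow(train_X)) {
    stop("`k` must be between 1 and the number of training rows", call. = FALSE)
  }
  D <- cross_distances(x, train_X, metric, whitener)
  apply_rows_knn(D, function(d, ord) mean(d[ord[seq_len(k)]]))
}

#' Local error: cross-validated RMSE of the k nearest neighbours
#'
#' Estimates the expected error at a query as the RMSE of the double-loop
#' cross-validated residuals of its `k` nearest training-set neighbours: if
#' a query resembles training compounds that were poorly predicted, the
#' model is likely to perform poorly on it too.
#'
#' @inheritParams knn_mean_distance
#' @param cv_table a [double_loop_cv()] table covering all training rows (in
#'   training-row order).
#' @return Numeric vector of local RMSEs, one per query row.
#' @export
local_error <- function(x, train_X, cv_table, k, metric = "euclidean",
                        whitener = NULL) {
  train_X <- as.matrix(train_X)
  if (nrow(cv_table) != nrow(train_X)) {
    stop("`cv_table` must cover all training rows", call. = FALSE)
  }
  if (k < 1L || k > nrow(train_X)) {
    stop("`k` must be between 1 and the number of training rows", call. = FALSE)
  }
  res <- cv_table$residual
  D <- cross_distances(x, train_X, metric, whitener)
  apply_rows_knn(D, function(d, ord) rmse(res[ord[seq_len(k)]]))
}

#' Ensemble spread at a query (bagged variance)
#'
#' The standard deviation (denominator `B - 1`) of the individual member
#' predictions of a bagged ensemble at each query compound. A large spread
#' signals that the model is not stable for the compound and corresponds to
#' a greater expected prediction error. For a `randomForest` model the
#' per-tree predictions serve directly as the ensemble.
#'
#' @param ensemble a [fit_bagged()] ensemble, or a `randomForest` model.
#' @param x query descriptor matrix (or single row).
#' @return Numeric vector of member-prediction standard deviations.
#' @export
bagged_variance_score <- function(ensemble, x) {
  x <- as_matrix_rows(x)
  if (inherits(ensemble, "bagged_ensemble")) {
    P <- member_predictions(ensemble, x)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  } else if (inherits(ensemble, "randomForest")) {
    P <- predict(ensemble, x, predict.all = TRUE)$individual
  } else {
    stop("`ensemble` must be a bagged_ensemble or randomForest", call. = FALSE)
  }
  if (ncol(P) < 2L) stop("ensemble must have >= 2 members", call. = FALSE)
  apply(P, 1L, sd)
}

#' Calibrate a reliability index against squared residuals
#'
#' Linear regression of squared prediction residuals on a reliability score
#' with the intercept fixed at the square of the experimental error, so that
#' `sigma_pred` equals the experimental error at a score of zero:
#' `sigma_pred(s) = sqrt(m * s + sigma_exp^2)`. With the intercept pinned,
#' the least-squares slope is
#' `m = sum(s_i (r_i^2 - sigma_exp^2)) / sum(s_i^2)`, clamped at zero so the
#' calibrated error is never decreasing in the score.
#'
#' @param scores nonnegative reliability scores (length >= 10).
#' @param residuals prediction residuals aligned with `scores`.
#' @param sigma_exp assay experimental error (fixes the intercept at
#'   `sigma_exp^2`).
#' @return An `error_calibration` with fields `slope`, `intercept`, `n`;
#'   `predict(cal, scores)` maps scores to `sigma_pred`.
#' @export
fit_error_regression <- function(scores, residuals, sigma_exp) {
  if (length(scores) != length(residuals)) {
    stop("`scores` and `residuals` must align", call. = FALSE)
  }
  if (length(scores) < 10L) {
    stop("need at least 10 parameterization points", call. = FALSE)
  }
  if (any(scores < 0)) stop("`scores` must be nonnegative", call. = FALSE)
  stopifnot_scalar_number(sigma_exp, "sigma_exp")
  if (all(scores == 0)) {
    stop("all scores are zero; the slope is undefined", call. = FALSE)
  }
  c0 <- sigma_exp^2
  m <- sum(scores * (residuals^2 - c0)) / sum(scores^2)
  structure(list(slope = max(m, 0), intercept = c0, n = length(scores)),
            class = "error_calibration")
}

#' Moving-block RMSE overlay for calibration plots
#'
#' Diagnostic companion to [fit_error_regression()]: residuals are ordered
#' by their reliability score and grouped into consecutive blocks, giving a
#' smoothed empirical RMSE curve to overlay on the fitted
#' `sqrt(m s + sigma_exp^2)` line. The regression itself is always fitted to
#' the per-compound squared residuals, never to this curve.
#'
#' @inheritParams fit_error_regression
#' @param block block size (default 50).
#' @return Data frame with one row per block: `mean_score`, `rmse`, `n`.
#' @export
moving_rmse <- function(scores, residuals, block = 50L) {
  if (length(scores) != length(residuals)) {
    stop("`scores` and `residuals` must align", call. = FALSE)
  }
  ord <- order(scores)
  idx <- bin_indices(length(scores), max(2L, block))
  do.call(rbind, lapply(idx, function(i) {
    data.frame(mean_score = mean(scores[ord][i]),
               rmse = rmse(residuals[ord][i]), n = length(i))
  }))
}

#' @export
predict.error_calibration <- function(object, newdata, ...) {
  if (any(newdata < 0)) stop("scores must be nonnegative", call. = FALSE)
  sqrt(object$slope * newdata + object$intercept)
}

#' @export
print.error_calibration <- function(x, ...) {
  cat(sprintf("<error_calibration> sigma_pred(s) = sqrt(%.4g s + %.4g)  [n = %d]\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}

# ---- error estimators -------------------------------------------------------

uniform_kinds <- c("TS", "CV")
variable_kinds <- c("D2M-EUC", "D2M-MD", "LE-EUC", "LE-MD",
                    "LEC-EUC", "LEC-MD", "BV", "BVC", "EM")

method_family <- function(tag) sub("-(EUC|MD)$", "", tag)
method_metric <- function(tag) {
  if (grepl("-MD$", tag)) "mahalanobis" else "euclidean"
}

#' Uniform error estimators (TS / CV)
#'
#' Uniform methods assign the same `sigma_pred` to every query: the RMSE of
#' a validation exercise. The temporal test-set (TS) flavour uses residuals
#' on a held-out parameterization test set; the cross-validation (CV)
#' flavour uses double-loop CV residuals on the training set. These serve as
#' the null hypotheses that any compound-specific method must beat.
#'
#' @param kind `"TS"` or `"CV"`.
#' @param predictions,observations aligned numeric vectors from the
#'   validation exercise (alternatively pass precomputed `residuals`).
#' @param residuals optional residual vector, used instead of
#'   `observations - predictions`.
#' @param sigma_floor error floor, normally the assay `sigma_exp`; emitted
#'   errors are never below it.
#' @return An `error_estimator`.
#' @export
make_uniform_estimator <- function(kind = c("TS", "CV"), predictions = NULL,
                                   observations = NULL, residuals = NULL,
                                   sigma_floor = 0) {
  kind <- match.arg(kind)
  if (is.null(residuals)) {
    if (is.null(predictions) || is.null(observations)) {
      stop("supply residuals, or predictions and observations", call. = FALSE)
    }
    if (length(predictions) != length(observations)) {
      stop("`predictions` and `observations` must align", call. = FALSE)
    }
    residuals <- observations - predictions
  }
  if (!length(residuals)) stop("no residuals supplied", call. = FALSE)
  new_error_estimator(method = kind, uniform_rmse = rmse(residuals),
                      sigma_floor = sigma_floor)
}

#' Variable error estimators (D2M / LE / LEC / BV / BVC / EM)
#'
#' Builds a compound-specific error estimator from its fitted components:
#' \describe{
#'   \item{D2M-EUC, D2M-MD}{mean k-NN distance passed through an
#'     [fit_error_regression()] calibration; needs `calibration`, `train_X`,
#'     `k`.}
#'   \item{LE-EUC, LE-MD}{raw local cross-validated RMSE of the k nearest
#'     neighbours; needs `train_X`, `cv_table`, `k`.}
#'   \item{LEC-EUC, LEC-MD}{local error passed through a calibration; needs
#'     additionally `calibration`.}
#'   \item{BV}{raw ensemble spread; needs `ensemble`.}
#'   \item{BVC}{ensemble spread through a calibration; needs `ensemble` and
#'     `calibration`.}
#'   \item{EM}{a second regression model predicting the absolute error;
#'     needs `error_model` (a fitted `qsar_model`). Negative predictions are
#'     floored at `sigma_floor`.}
#' }
#' All emitted errors are floored at `sigma_floor` (normally the assay
#' experimental error).
#'
#' @param method one of the tags above.
#' @param sigma_floor positive error floor.
#' @param k neighbour count for the distance-based families.
#' @param calibration an `error_calibration` (D2M/LEC/BVC).
#' @param train_X standardised training descriptor matrix (D2M/LE/LEC).
#' @param cv_table [double_loop_cv()] table aligned to `train_X` (LE/LEC).
#' @param ensemble [fit_bagged()] ensemble or `randomForest` (BV/BVC).
#' @param error_model fitted absolute-error model (EM).
#' @return An `error_estimator`; obtain errors with
#'   [estimate_sigma()].
#' @export
make_variable_estimator <- function(method, sigma_floor, k = NULL,
                                    calibration = NULL, train_X = NULL,
                                    cv_table = NULL, ensemble = NULL,
                                    error_model = NULL) {
  if (!method %in% variable_kinds) {
    stop(sprintf("unknown error-estimation method '%s'", method), call. = FALSE)
  }
  fam <- method_family(method)
  need <- function(ok, what) {
    if (!ok) stop(sprintf("method %s requires %s", method, what), call. = FALSE)
  }
  if (fam %in% c("D2M", "LE", "LEC")) {
    need(!is.null(train_X), "`train_X`")
    need(!is.null(k), "`k`")
  }
  if (fam %in% c("LE", "LEC")) need(!is.null(cv_table), "`cv_table`")
  if (fam %in% c("D2M", "LEC")) need(!is.null(calibration), "`calibration`")
  if (fam %in% c("BV", "BVC")) need(!is.null(ensemble), "`ensemble`")
  if (fam == "BVC") need(!is.null(calibration), "`calibration`")
  if (fam == "EM") need(!is.null(error_model), "`error_model`")
  whitener <- NULL
  if (!is.null(train_X) && method_metric(method) == "mahalanobis") {
    whitener <- mahalanobis_whitener(train_X)
  }
  new_error_estimator(method = method, sigma_floor = sigma_floor, k = k,
                      calibration = calibration, train_X = train_X,
                      cv_table = cv_table, ensemble = ensemble,
                      error_model = error_model, whitener = whitener)
}

new_error_estimator <- function(method, sigma_floor = 0, uniform_rmse = NULL,
                                k = NULL, calibration = NULL, train_X = NULL,
                                cv_table = NULL, ensemble = NULL,
                                error_model = NULL, whitener = NULL) {
  structure(list(method = method, sigma_floor = sigma_floor,
                 uniform_rmse = uniform_rmse, k = k,
                 calibration = calibration, train_X = train_X,
                 cv_table = cv_table, ensemble = ensemble,
                 error_model = error_model, whitener = whitener),
            class = "error_estimator")
}

#' @export
print.error_estimator <- function(x, ...) {
  cat("<error_estimator>", x$method)
  if (!is.null(x$uniform_rmse)) cat(sprintf("  RMSE = %.4g", x$uniform_rmse))
  if (!is.null(x$k)) cat(sprintf("  k = %d", x$k))
  if (!is.null(x$calibration)) {
    cat(sprintf("  sigma(s) = sqrt(%.4g s + %.4g)",
                x$calibration$slope, x$calibration$intercept))
  }
  cat(sprintf("  floor = %.4g\n", x$sigma_floor))
  invisible(x)
}

#' Estimate prediction errors for query compounds
#'
#' Maps each query to its `sigma_pred` under the estimator's method, then
#' applies the error floor. Query descriptors must be on the same
#' (standardised) scale as the estimator's training context.
#'
#' @param estimator an `error_estimator`.
#' @param x query descriptor matrix (or single row); may be omitted for
#'   uniform estimators when `n` is given.
#' @param n number of queries (uniform estimators without `x`).
#' @return Numeric vector of floored `sigma_pred` values.
#' @export
estimate_sigma <- function(estimator, x = NULL, n = NULL) {
  stopifnot(inherits(estimator, "error_estimator"))
  fam <- method_family(estimator$method)
  metric <- method_metric(estimator$method)
  raw <- switch(
    fam,
    TS = ,
    CV = {
      n <- n %||% (if (is.null(x)) stop("need `x` or `n`", call. = FALSE)
                   else nrow(as_matrix_rows(x)))
      rep(estimator$uniform_rmse, n)
    },
    D2M = {
      s <- knn_mean_distance(x, estimator$train_X, estimator$k, metric,
                             estimator$whitener)
      predict(estimator$calibration, s)
    },
    LE = local_error(x, estimator$train_X, estimator$cv_table, estimator$k,
                     metric, estimator$whitener),
    LEC = {
      s <- local_error(x, estimator$train_X, estimator$cv_table, estimator$k,
                       metric, estimator$whitener)
      predict(estimator$calibration, s)
    },
    BV = bagged_variance_score(estimator$ensemble, x),
    BVC = {
      s <- bagged_variance_score(estimator$ensemble, x)
      predict(estimator$calibration, s)
    },
    EM = pmax(predict(estimator$error_model, x), 0),
    stop("unreachable")
  )
  if (estimator$sigma_floor > 0) {
    apply_sigma_floor(raw, estimator$sigma_floor)
  } else {
    raw
  }
}

#' Refresh an estimator's data context, keeping calibration frozen
#'
#' Under the growing-window protocol the calibration parameters (`m`, `c`,
#' `k`, uniform RMSE) are fitted once on the parameterization test set and
#' frozen, while the data context (training matrix, CV table, ensemble) is
#' rebuilt at every monthly retraining. This helper swaps the context
#' without touching the frozen parameters.
#'
#' @param estimator an `error_estimator`.
#' @param train_X,cv_table,ensemble,error_model replacement context
#'   components (only those supplied are replaced).
#' @return The updated estimator.
#' @export
refresh_estimator <- function(estimator, train_X = NULL, cv_table = NULL,
                              ensemble = NULL, error_model = NULL) {
  stopifnot(inherits(estimator, "error_estimator"))
  if (!is.null(train_X)) {
    estimator$train_X <- train_X
    if (method_metric(estimator$method) == "mahalanobis") {
      estimator$whitener <- mahalanobis_whitener(train_X)
    }
  }
  if (!is.null(cv_table)) estimator$cv_table <- cv_table
  if (!is.null(ensemble)) estimator$ensemble <- ensemble
  if (!is.null(error_model)) estimator$error_model <- error_model
  estimator
}

#' Choose the neighbour count k by mean KL on the parameterization set
#'
#' Evaluates each candidate `k` by the mean KL divergence of the resulting
#' predictive distributions against the parameterization-set measurement
#' distributions, and returns the minimiser (ties go to the smallest `k`).
#' Candidates exceeding the training-set size are dropped first.
#'
#' @param candidate_ks integer candidates (default spans 1 to 200).
#' @param sigma_for_k function mapping a single `k` to the vector of
#'   (pre-floor) `sigma_pred` values on the parameterization set.
#' @param observed `gaussian_dist` of parameterization measurement
#'   distributions.
#' @param mu_pred point predictions on the parameterization set.
#' @param sigma_floor error floor applied before scoring.
#' @param n_train training-set size used to filter candidates.
#' @return The selected `k` (integer) with the per-candidate mean-KL table
#'   attached as attribute `"kl"`.
#' @export
optimize_k <- function(candidate_ks = c(1L, 2L, 3L, 5L, 8L, 12L, 20L, 50L,
                                        100L, 200L),
                       sigma_for_k, observed, mu_pred, sigma_floor,
                       n_train = Inf) {
  ks <- sort(unique(as.integer(candidate_ks)))
  ks <- ks[ks >= 1L & ks <= n_train]
  if (!length(ks)) stop("no feasible k candidates remain", call. = FALSE)
  kl <- vapply(ks, function(k) {
    sig <- apply_sigma_floor(sigma_for_k(k), sigma_floor)
    mean_kl(observed, gaussian_dist(mu_pred, sig))
  }, numeric(1))
  best <- ks[which.min(kl)] # which.min takes the first minimum: smallest k
  attr(best, "kl") <- data.frame(k = ks, mean_kl = kl)
  best
}
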