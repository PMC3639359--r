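#' Compose a model and an error estimator into a PD method
#'
#' A Predictive Distribution (PD) method pairs a fitted point-prediction
#' model with an error-estimation method: the model supplies the mean
#' `mu_pred` and the estimator the standard deviation `sigma_pred` of a
#' Gaussian predictive distribution. The error floor (normally the assay
#' experimental error) guarantees the emitted `sigma` never undercuts the
#' measurement error.
#'
#' @param model fitted `qsar_model` or `bagged_ensemble`.
#' @param estimator an `error_estimator`.
#' @param sigma_floor positive floor; defaults to the estimator's own floor.
#' @param scaler optional [descriptor_scaler()]; when present, raw query
#'   descriptors are standardised before prediction and error estimation.
#' @param label method label; defaults to `"{ALGORITHM}:{ERRORMETHOD}"`
#'   (e.g. `"ridge:D2M-EUC"`).
#' @return A `pd_method`.
#' @export
pd_method <- function(model, estimator, sigma_floor = NULL, scaler = NULL,
                      label = NULL) {
  stopifnot(inherits(estimator, "error_estimator"))
  sigma_floor <- sigma_floor %||% estimator$sigma_floor
  if (!is.numeric(sigma_floor) || sigma_floor <= 0) {
    stop("`sigma_floor` must be positive", call. = FALSE)
  }
  estimator$sigma_floor <- sigma_floor
  algo <- if (!is.null(model$algorithm)) model$algorithm else class(model)[1L]
  structure(list(model = model, estimator = estimator,
                 sigma_floor = sigma_floor, scaler = scaler,
                 label = label %||% paste0(algo, ":", estimator$method)),
            class = "pd_method")
}

#' @export
print.pd_method <- function(x, ...) {
  cat("<pd_method>", x$label, sprintf(" floor = %.4g\n", x$sigma_floor))
  invisible(x)
}

#' Predict Gaussian distributions for query compounds
#'
#' @param pd a [pd_method()].
#' @param x query descriptor matrix (raw layout if the method holds a
#'   scaler, otherwise already standardised); rows are preserved in input
#'   order.
#' @return A `gaussian_dist` of length `nrow(x)`.
#' @export
predict_distribution <- function(pd, x) {
  stopifnot(inherits(pd, "pd_method"))
  x <- as_matrix_rows(x)
  if (!is.null(pd$scaler)) x <- apply_scaler(pd$scaler, x)
  mu <- predict(pd$model, x)
  sigma <- estimate_sigma(pd$estimator, x)
  gaussian_dist(mu, apply_sigma_floor(sigma, pd$sigma_floor))
}

#' Normalized prediction errors
#'
#' `(mu_obs - mu_pred) / sigma_pred`: the residual divided by its estimated
#' error. For well-specified predictive distributions the normalized errors
#' are approximately standard normal, which [normality_diagnostics()]
#' checks.
#'
#' @param obs measurement distributions (`gaussian_dist`).
#' @param pred predictive distributions (`gaussian_dist`, same length).
#' @return Numeric vector of signed z-like scores.
#' @export
normalized_error <- function(obs, pred) {
  if (!is_gaussian_dist(obs) || !is_gaussian_dist(pred)) {
    stop("`obs` and `pred` must be gaussian_dist objects", call. = FALSE)
  }
  if (length(obs) != length(pred)) {
    stop("`obs` and `pred` must have equal length", call. = FALSE)
  }
  (obs$mu - pred$mu) / pred$sigma
}
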