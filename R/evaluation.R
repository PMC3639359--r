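# KL-based and calibration diagnostics over test sets.

#' Faber confidence interval for an RMSE
#'
#' Distribution-based approximation of the sampling error of an RMSE over
#' `n` residuals: `sd(RMSE)/RMSE ~ (1/(2n))^(1/2)`. The 95% interval uses
#' the normal multiplier 1.96 and is floored at zero.
#'
#' @param rmse nonnegative RMSE value.
#' @param n number of residuals behind it (>= 1).
#' @return Named vector `c(lower, upper)`.
#' @export
faber_rmse_ci <- function(rmse, n) {
  if (length(n) != 1L || n < 1) stop("`n` must be a positive count", call. = FALSE)
  if (rmse < 0) stop("`rmse` must be nonnegative", call. = FALSE)
  hw <- 1.96 * rmse * sqrt(1 / (2 * n))
  c(lower = max(rmse - hw, 0), upper = rmse + hw)
}

#' Bin predictions by their estimated error
#'
#' Ranks test-set predictions by `sigma_pred` (ascending; ties break by
#' input index) and groups them into bins of `bin_size` compounds, so each
#' bin holds predictions with similar estimated errors. Per bin it reports
#' the estimated RMSE (the root mean square of the `sigma_pred` values), the
#' observed RMSE of the residuals, the Faber 95% CI of the estimated RMSE,
#' whether the observed RMSE falls inside that interval, and the mean KL
#' divergence. A final partial bin is merged into the preceding bin; if
#' fewer than `bin_size` predictions are supplied a single bin is returned
#' with a warning.
#'
#' @param predicted predictive distributions (`gaussian_dist`).
#' @param observed measurement distributions (`gaussian_dist`, aligned).
#' @param bin_size compounds per bin (>= 2).
#' @return A data frame of class `error_bins`, one row per bin, with an
#'   attribute `"order"` giving the ranking permutation.
#' @export
bin_by_estimated_error <- function(predicted, observed, bin_size) {
  if (!is_gaussian_dist(predicted) || !is_gaussian_dist(observed)) {
    stop("`predicted` and `observed` must be gaussian_dist objects", call. = FALSE)
  }
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must align", call. = FALSE)
  }
  if (bin_size < 2L) stop("`bin_size` must be >= 2", call. = FALSE)
  n <- length(predicted)
  if (n < bin_size) {
    warning("fewer predictions than bin_size; returning a single bin")
  }
  ord <- order(predicted$sigma)
  kl <- kl_gaussian(observed, predicted)[ord]
  res <- (observed$mu - predicted$mu)[ord]
  sig <- predicted$sigma[ord]
  idx <- bin_indices(n, bin_size)
  rows <- lapply(seq_along(idx), function(b) {
    i <- idx[[b]]
    est <- sqrt(mean(sig[i]^2))
    obs <- rmse(res[i])
    ci <- faber_rmse_ci(est, length(i))
    data.frame(bin = b, n = length(i), estimated_rmse = est,
               observed_rmse = obs, ci_lower = ci[["lower"]],
               ci_upper = ci[["upper"]],
               within_ci = obs >= ci[["lower"]] & obs <= ci[["upper"]],
               mean_kl = mean(kl[i]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("error_bins", class(out))
  attr(out, "order") <- ord
  out
}

#' Per-bin KL difference of a variable method against a uniform baseline
#'
#' Bins the test set by the VARIABLE method's estimated errors and reports,
#' per bin, the difference in mean KL divergence between the variable and
#' uniform predictions of the same observations. A negative difference means
#' the variable error-estimation method delivered an information gain for
#' that bin; the gains are typically largest in the highest estimated-error
#' bins, where recognising unreliable predictions matters most.
#'
#' @param variable_pred,uniform_pred aligned predictive distributions from
#'   the variable method and the uniform baseline.
#' @param observed aligned measurement distributions.
#' @param bin_size compounds per bin.
#' @return Data frame per bin: `bin`, `n`, `mean_sigma_pred`, `kl_variable`,
#'   `kl_uniform`, `kl_diff` (variable - uniform).
#' @export
kl_difference_profile <- function(variable_pred, uniform_pred, observed,
                                  bin_size) {
  ns <- c(length(variable_pred), length(uniform_pred), length(observed))
  if (length(unique(ns)) != 1L) {
    stop("prediction sets and observations must align", call. = FALSE)
  }
  ord <- order(variable_pred$sigma)
  klv <- kl_gaussian(observed, variable_pred)[ord]
  klu <- kl_gaussian(observed, uniform_pred)[ord]
  sig <- variable_pred$sigma[ord]
  idx <- bin_indices(ns[1L], bin_size)
  rows <- lapply(seq_along(idx), function(b) {
    i <- idx[[b]]
    data.frame(bin = b, n = length(i), mean_sigma_pred = mean(sig[i]),
               kl_variable = mean(klv[i]), kl_uniform = mean(klu[i]),
               kl_diff = mean(klv[i]) - mean(klu[i]))
  })
  do.call(rbind, rows)
}

#' Normality diagnostics for normalized errors
#'
#' One-sample Kolmogorov-Smirnov test of the normalized errors against the
#' standard normal, plus histogram data with a unit-Gaussian overlay for
#' plotting. For well-specified predictive distributions the normalized
#' errors should be close to N(0, 1). Constant input is degenerate: the KS
#' statistic approaches the maximum CDF range and the test is meaningless
#' (ties are reported by `ks.test` via a warning).
#'
#' @param normalized_errors numeric vector, length >= 8.
#' @param breaks histogram break specification (passed to [graphics::hist]).
#' @return List with `statistic`, `p_value`, `histogram` (a `histogram`
#'   object computed without plotting) and `overlay` (data frame `x`,
#'   `density` of the standard normal).
#' @export
normality_diagnostics <- function(normalized_errors, breaks = "Sturges") {
  if (length(normalized_errors) < 8L) {
    stop("need at least 8 normalized errors", call. = FALSE)
  }
  ks <- suppressWarnings(ks.test(normalized_errors, "pnorm"))
  h <- graphics::hist(normalized_errors, breaks = breaks, plot = FALSE)
  xs <- seq(min(h$breaks), max(h$breaks), length.out = 200L)
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       histogram = h, overlay = data.frame(x = xs, density = dnorm(xs)))
}
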