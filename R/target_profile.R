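#' Target property profiles
#'
#' A target profile lists one interval per endpoint that a compound must
#' satisfy, e.g. LogD in \[1.5, 2.5\] and Caco2 permeability above -5 log
#' cm/s. Use `-Inf` / `Inf` for one-sided bounds.
#'
#' @param lower,upper numeric vectors of per-endpoint bounds
#'   (`lower < upper` elementwise).
#' @param labels optional endpoint labels.
#' @return A `target_profile` data frame with columns `label`, `lower`,
#'   `upper`.
#' @export
target_profile <- function(lower, upper, labels = NULL) {
  if (length(lower) != length(upper) || !length(lower)) {
    stop("`lower` and `upper` must be non-empty and aligned", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("each component needs lower < upper", call. = FALSE)
  }
  labels <- labels %||% paste0("endpoint", seq_along(lower))
  structure(data.frame(label = labels, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("target_profile", "data.frame"))
}

#' Probability that a prediction falls in a target range
#'
#' The proportion of a Gaussian predictive distribution lying inside
#' `[lower, upper]`, from the Gaussian CDF:
#' `Phi((upper - mu)/sigma) - Phi((lower - mu)/sigma)`. Infinite bounds give
#' one-sided profiles. Vectorised over predictions.
#'
#' @param pred predictive distributions (`gaussian_dist`).
#' @param lower,upper profile bounds with `lower < upper`.
#' @return Probabilities in `[0, 1]`.
#' @export
hit_probability <- function(pred, lower, upper) {
  if (!is_gaussian_dist(pred)) stop("`pred` must be a gaussian_dist", call. = FALSE)
  if (any(lower >= upper)) stop("`lower` must be below `upper`", call. = FALSE)
  pnorm((upper - pred$mu) / pred$sigma) - pnorm((lower - pred$mu) / pred$sigma)
}

#' Joint probability of hitting a multi-objective profile
#'
#' Multiplies the per-endpoint hit probabilities, treating endpoint
#' predictions as independent (the predictive distributions come from
#' separate single-endpoint models).
#'
#' @param preds list of `gaussian_dist` objects, one per profile component,
#'   all of equal length (compounds).
#' @param profile a [target_profile()] with the same number of components.
#' @return Probabilities in `[0, 1]`, one per compound.
#' @export
multi_objective_probability <- function(preds, profile) {
  if (!inherits(profile, "target_profile")) {
    stop("`profile` must be a target_profile", call. = FALSE)
  }
  if (!is.list(preds) || length(preds) != nrow(profile)) {
    stop("need one prediction set per profile component", call. = FALSE)
  }
  ns <- vapply(preds, length, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all prediction sets must have equal length", call. = FALSE)
  }
  comps <- lapply(seq_len(nrow(profile)), function(i) {
    hit_probability(preds[[i]], profile$lower[i], profile$upper[i])
  })
  Reduce(`*`, comps)
}

#' Calibration table for estimated hit probabilities
#'
#' Ranks compounds by their estimated probability of hitting the profile,
#' bins them in full bins of `bin_size` (a final partial bin is merged into
#' the preceding one), and compares the mean estimated probability to the
#' observed hit fraction per bin. The 95% confidence interval of the
#' observed fraction comes from the central limit theorem and is flagged
#' reliable only when the bin contains more than 5 hits.
#'
#' @param probabilities estimated hit probabilities in `[0, 1]`.
#' @param hits logical vector of observed outcomes, aligned.
#' @param bin_size compounds per bin, at least 2.
#' @return A data frame with one row per bin: `bin`, `n`, `mean_probability`,
#'   `observed_rate`, `n_hits`, `ci_lower`, `ci_upper`, `ci_valid`.
#'   Attributes `overall_rate` (observed hit fraction over all compounds)
#'   and `n_total`.
#' @export
probability_calibration <- function(probabilities, hits, bin_size = 50L) {
  if (!length(probabilities)) stop("empty input", call. = FALSE)
  if (length(probabilities) != length(hits)) {
    stop("`probabilities` and `hits` must align", call. = FALSE)
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (bin_size < 2L) stop("`bin_size` must be >= 2", call. = FALSE)
  hits <- as.logical(hits)
  ord <- order(probabilities) # stable: ties keep input order
  p <- probabilities[ord]
  h <- hits[ord]
  idx <- bin_indices(length(p), bin_size)
  rows <- lapply(seq_along(idx), function(b) {
    i <- idx[[b]]
    obs <- mean(h[i])
    se <- sqrt(obs * (1 - obs) / length(i))
    data.frame(bin = b, n = length(i), mean_probability = mean(p[i]),
               observed_rate = obs, n_hits = sum(h[i]),
               ci_lower = max(obs - 1.96 * se, 0),
               ci_upper = min(obs + 1.96 * se, 1),
               ci_valid = sum(h[i]) > 5L)
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_rate") <- mean(hits)
  attr(out, "n_total") <- length(hits)
  out
}

# Contiguous bins of bin_size over n ranked items; a final partial bin is
# merged into the preceding full bin.
bin_indices <- function(n, bin_size) {
  if (n <= bin_size) return(list(seq_len(n)))
  n_full <- n %/% bin_size
  idx <- split(seq_len(n_full * bin_size),
               rep(seq_len(n_full), each = bin_size))
  rest <- seq_len(n)[-seq_len(n_full * bin_size)]
  if (length(rest)) idx[[n_full]] <- c(idx[[n_full]], rest)
  unname(idx)
}
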