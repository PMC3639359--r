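#' Pooled single-shot experimental error from QC replicates
#'
#' Quality-control (QC) compounds are assayed repeatedly to monitor assay
#' consistency; the pooled root-mean-square deviation of each QC compound's
#' measurements from its own mean estimates the single-shot experimental
#' error `sigma_exp`:
#' `sigma_exp = sqrt( sum_ij (QC_ij - mean(QC_i))^2 / sum_i N_i )`.
#'
#' The denominator is the total number of measurements, with no
#' degrees-of-freedom correction (maximum-likelihood pooling); the estimate
#' is therefore slightly biased low for small replicate counts. QC compounds
#' with a single measurement carry no variance information and are excluded.
#'
#' @param qc data frame with columns `compound_id` and `value`, one row per
#'   QC measurement.
#' @return The pooled `sigma_exp` estimate (single number).
#' @examples
#' qc <- data.frame(compound_id = c("a", "a"), value = c(-1, 1))
#' experimental_error_from_qc(qc) # 1
#' @export
experimental_error_from_qc <- function(qc) {
  if (!is.data.frame(qc) || !all(c("compound_id", "value") %in% names(qc))) {
    stop("`qc` must be a data frame with columns compound_id and value",
         call. = FALSE)
  }
  qc$value <- as.numeric(qc$value)
  if (any(!is.finite(qc$value))) {
    stop("QC values must be finite numbers", call. = FALSE)
  }
  counts <- table(qc$compound_id)
  singletons <- names(counts)[counts < 2L]
  if (length(singletons)) {
    warning(sprintf(
      "dropping %d QC compound(s) with a single measurement: %s",
      length(singletons), paste(singletons, collapse = ", ")))
    qc <- qc[!(qc$compound_id %in% singletons), , drop = FALSE]
  }
  if (nrow(qc) < 2L) {
    stop("need at least one QC compound with >= 2 measurements", call. = FALSE)
  }
  dev <- qc$value - ave(qc$value, qc$compound_id)
  if (all(dev == 0)) {
    warning("all QC replicates identical within compounds; sigma_exp = 0 is degenerate")
  }
  sqrt(sum(dev^2) / nrow(qc))
}

#' Standard error of a compound's mean measurement
#'
#' The error on the mean of `n` replicate measurements is
#' `sigma_obs = sigma_exp / sqrt(n)`.
#'
#' @param sigma_exp single-shot assay error (> 0).
#' @param n_measurements replicate count(s), integer >= 1 (vectorised).
#' @return `sigma_exp / sqrt(n_measurements)`.
#' @export
sigma_obs <- function(sigma_exp, n_measurements) {
  stopifnot_scalar_number(sigma_exp, "sigma_exp")
  if (sigma_exp <= 0) stop("`sigma_exp` must be positive", call. = FALSE)
  if (any(n_measurements < 1) || any(n_measurements != floor(n_measurements))) {
    stop("`n_measurements` must be integers >= 1", call. = FALSE)
  }
  sigma_exp / sqrt(n_measurements)
}

#' Build per-compound measurement distributions from a replicate table
#'
#' Groups a measurement table by compound, averages the (possibly qualified)
#' replicate values into `mu_obs`, and assigns
#' `sigma_obs = sigma_exp / sqrt(n)`. Non-QC compounds inherit the QC-derived
#' assay error. Qualified values such as `">5"` are used numerically with the
#' qualifier stripped; rows whose value cannot be parsed are dropped with a
#' warning.
#'
#' @param measurements data frame with columns `compound_id` and `value`
#'   (numeric, or character possibly carrying `<`, `>`, `<=`, `>=`
#'   qualifiers). Additional columns are ignored.
#' @param sigma_exp single-shot assay error from
#'   [experimental_error_from_qc()].
#' @return A data frame with one row per compound: `compound_id`, `mu_obs`,
#'   `sigma_obs`, `n_measurements`, plus an `observed` attribute holding the
#'   matching `gaussian_dist`.
#' @export
build_measurement_distributions <- function(measurements, sigma_exp) {
  if (!is.data.frame(measurements) ||
      !all(c("compound_id", "value") %in% names(measurements))) {
    stop("`measurements` needs columns compound_id and value", call. = FALSE)
  }
  stopifnot_scalar_number(sigma_exp, "sigma_exp")
  # the row-level warning below supersedes the parser's own
  parsed <- suppressWarnings(parse_qualified_value(as.character(measurements$value)))
  bad <- is.na(parsed$value)
  if (any(bad)) {
    warning(sprintf("dropping %d unparseable measurement value(s) (rows %s)",
                    sum(bad), paste(utils::head(which(bad), 5L), collapse = ", ")))
  }
  keep <- measurements[!bad, , drop = FALSE]
  keep$.value <- parsed$value[!bad]
  if (nrow(keep) == 0L) stop("no parseable measurement values", call. = FALSE)
  agg <- aggregate(.value ~ compound_id, data = keep, FUN = mean)
  n <- aggregate(.value ~ compound_id, data = keep, FUN = length)
  out <- data.frame(
    compound_id = agg$compound_id,
    mu_obs = agg$.value,
    sigma_obs = sigma_obs(sigma_exp, n$.value),
    n_measurements = n$.value,
    stringsAsFactors = FALSE
  )
  attr(out, "observed") <- gaussian_dist(out$mu_obs, out$sigma_obs)
  out
}
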