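# Tabular readers/writers and estimator persistence. CSV dialect: comma
# separated, UTF-8, header row, ISO-8601 dates; "-inf"/"inf" sentinels are
# accepted for profile bounds.

#' Read the standard tables
#'
#' `read_measurement_table()` expects columns `compound_id`, `date`,
#' `value` (string, possibly qualified) and optionally `excluded`;
#' `read_qc_table()` expects `compound_id`, `value`;
#' `read_descriptor_table()` expects a `compound_id` column followed by
#' numeric descriptor columns and returns a matrix with id rownames.
#'
#' @param path CSV file path.
#' @return Data frame, or a numeric matrix for descriptors.
#' @export
read_measurement_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(value = "character"))
  need <- c("compound_id", "date", "value")
  if (!all(need %in% names(d))) {
    stop("measurement table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' @rdname read_measurement_table
#' @export
read_qc_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "value") %in% names(d))) {
    stop("QC table needs columns compound_id, value", call. = FALSE)
  }
  d
}

#' @rdname read_measurement_table
#' @export
read_descriptor_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"compound_id" %in% names(d)) {
    stop("descriptor table needs a compound_id column", call. = FALSE)
  }
  X <- as.matrix(d[, setdiff(names(d), "compound_id"), drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- d$compound_id
  X
}

#' Write a synthetic dataset to a directory
#'
#' Emits `measurements.csv`, `descriptors.csv`, `qc.csv`, `truth.csv` and a
#' `generator.json` sidecar carrying the generator parameters, in the same
#' dialects the harness readers consume.
#'
#' @param dataset a [generate_synthetic()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  desc <- data.frame(compound_id = rownames(dataset$descriptors),
                     dataset$descriptors, check.names = FALSE)
  utils::write.csv(desc, file.path(dir, "descriptors.csv"), row.names = FALSE)
  utils::write.csv(dataset$qc, file.path(dir, "qc.csv"), row.names = FALSE)
  utils::write.csv(dataset$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  side <- c(unclass(dataset$config),
            list(param_start = as.character(dataset$param_start),
                 test_start = as.character(dataset$test_start)))
  jsonlite::write_json(side, file.path(dir, "generator.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Persist frozen error-estimator parameters as JSON
#'
#' Stores the method tag and its frozen parameters (`k`, regression slope
#' and intercept, uniform RMSE, floor) so an estimator can be rebuilt over a
#' fresh data context in a later session with [refresh_estimator()].
#'
#' @param estimator an `error_estimator`.
#' @param path JSON file path.
#' @return Invisibly, `path`.
#' @export
serialize_estimator <- function(estimator, path) {
  stopifnot(inherits(estimator, "error_estimator"))
  state <- list(method = estimator$method,
                sigma_floor = estimator$sigma_floor,
                uniform_rmse = estimator$uniform_rmse, k = estimator$k,
                slope = estimator$calibration$slope,
                intercept = estimator$calibration$intercept)
  jsonlite::write_json(state[!vapply(state, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname serialize_estimator
#' @return `deserialize_estimator()` returns an `error_estimator` whose data
#'   context (training matrix, CV table, ensemble) must be supplied through
#'   [refresh_estimator()] before use on the variable methods.
#' @export
deserialize_estimator <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  cal <- NULL
  if (!is.null(s$slope)) {
    cal <- structure(list(slope = s$slope, intercept = s$intercept, n = NA_integer_),
                     class = "error_calibration")
  }
  new_error_estimator(method = s$method, sigma_floor = s$sigma_floor %||% 0,
                      uniform_rmse = s$uniform_rmse,
                      k = if (!is.null(s$k)) as.integer(s$k),
                      calibration = cal)
}

#' Write pooled PD-method predictions
#'
#' One row per compound and method: `compound_id`, `month`, `method`,
#' `mu_pred`, `sigma_pred`, `mu_obs`, `sigma_obs`.
#'
#' @param predictions the long prediction table from [run_growing_window()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}

parse_bound <- function(x) {
  if (is.numeric(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  if (x %in% c("inf", "+inf")) return(Inf)
  if (x == "-inf") return(-Inf)
  as.numeric(x)
}
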