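# Temporal validation protocol: qualified-value handling, training-set
# reduction, splits, and the growing-window harness.

#' Parse possibly qualified measurement values
#'
#' Assay results reported as inequalities (e.g. `">5"`, `"<=-1.4"`) are used
#' as quantitative measurements with the qualifying symbol stripped; the
#' qualifier is retained as metadata. Unparseable strings yield `NA` with a
#' warning identifying the rows.
#'
#' @param raw character vector of raw value strings (plain numerals are
#'   passed through).
#' @return Data frame with columns `value` (numeric, `NA` when unparseable)
#'   and `qualifier` (`""`, `"<"`, `">"`, `"<="`, `">="`).
#' @export
parse_qualified_value <- function(raw) {
  raw <- as.character(raw)
  m <- regmatches(raw, regexec(
    "^\\s*(<=|>=|<|>)?\\s*([+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?)\\s*$",
    raw))
  qualifier <- vapply(m, function(g) if (length(g)) g[2L] else NA_character_,
                      character(1))
  value <- vapply(m, function(g) if (length(g)) as.numeric(g[3L]) else NA_real_,
                  numeric(1))
  bad <- is.na(value)
  if (any(bad)) {
    warning(sprintf("could not parse %d value(s), e.g. rows %s",
                    sum(bad), paste(utils::head(which(bad), 5L), collapse = ", ")))
    qualifier[bad] <- NA_character_
  }
  data.frame(value = value, qualifier = qualifier, stringsAsFactors = FALSE)
}

#' Reduce a large training set to recent plus random compounds
#'
#' Training sets larger than `cap` compounds are reduced to the `recent`
#' most recent compounds plus a without-replacement random sample of
#' `random_n` of the remainder; smaller sets pass through unchanged. With a
#' fixed seed the subset is reproducible.
#'
#' @param records data frame with a `date` column (sortable).
#' @param cap maximum size before reduction kicks in (default 35,000).
#' @param recent number of most recent compounds always kept (default
#'   20,000).
#' @param random_n number of randomly sampled older compounds (default
#'   15,000).
#' @param seed optional integer seed for the random sample.
#' @return The (possibly reduced) records, in their original relative order.
#' @export
reduce_training_set <- function(records, cap = 35000L, recent = 20000L,
                                random_n = 15000L, seed = NULL) {
  if (cap < recent + random_n) {
    stop("`cap` must be at least `recent + random_n`", call. = FALSE)
  }
  if (!"date" %in% names(records)) stop("records need a `date` column", call. = FALSE)
  n <- nrow(records)
  if (n <= cap) return(records)
  ord <- order(records$date, decreasing = TRUE)
  newest <- ord[seq_len(recent)]
  older <- ord[-seq_len(recent)]
  sampled <- with_seed(seed, sample(older, random_n))
  keep <- sort(c(newest, sampled))
  records[keep, , drop = FALSE]
}

#' Split compound records into temporal subsets
#'
#' Chronological three-way split: an initial training set (before
#' `param_start`), a parameterization test set (`[param_start, test_start)`)
#' used once to fit error-estimation parameters, and consecutive monthly
#' experimental test windows from `test_start` onwards.
#'
#' @param dates vector of dates (`Date` or coercible).
#' @param param_start first date of the parameterization window.
#' @param test_start first date of the first monthly test window.
#' @return List with `train_idx`, `param_idx` and `months` (named list of
#'   index vectors keyed `"YYYY-MM"`, chronological).
#' @export
temporal_split <- function(dates, param_start, test_start) {
  dates <- as.Date(dates)
  param_start <- as.Date(param_start)
  test_start <- as.Date(test_start)
  if (param_start >= test_start) {
    stop("`param_start` must precede `test_start`", call. = FALSE)
  }
  train_idx <- which(dates < param_start)
  param_idx <- which(dates >= param_start & dates < test_start)
  test_idx <- which(dates >= test_start)
  keys <- format(dates[test_idx], "%Y-%m")
  months <- split(test_idx, keys)
  months <- months[order(names(months))]
  list(train_idx = train_idx, param_idx = param_idx, months = months)
}

#' Combined test-window bookkeeping
#'
#' Sums per-window compound counts into combined test-set totals, as
#' reported for a pooled evaluation across all monthly windows.
#'
#' @param counts data frame of per-window counts; all numeric columns are
#'   summed (a `month`/`window` label column is ignored).
#' @return Named numeric vector of combined totals per endpoint column.
#' @export
combine_test_window_counts <- function(counts) {
  num <- vapply(counts, is.numeric, logical(1))
  if (!any(num)) stop("no numeric count columns", call. = FALSE)
  colSums(as.data.frame(counts)[, num, drop = FALSE])
}

#' Monthly experimental test-set sizes of a year-long ADME benchmark
#'
#' Example bookkeeping table: the number of test compounds per monthly
#' window (April 2011 to January 2012) for three pharmacokinetic assay
#' endpoints - octanol/water distribution (logd), human plasma protein
#' binding (hppb) and Caco2 A-to-B permeability (caco2) - used in examples
#' and in tests of the combined-count bookkeeping.
#'
#' @return Data frame with columns `month`, `logd`, `hppb`, `caco2`.
#' @export
example_monthly_counts <- function() {
  data.frame(
    month = c("2011-04", "2011-05", "2011-06", "2011-07", "2011-08",
              "2011-09", "2011-10", "2011-11", "2011-12", "2012-01"),
    logd = c(879, 765, 923, 848, 932, 866, 780, 392, 739, 984),
    hppb = c(649, 491, 293, 451, 517, 503, 415, 426, 639, 408),
    caco2 = c(68, 171, 178, 80, 64, 109, 249, 278, 189, 84),
    stringsAsFactors = FALSE
  )
}

# ---- growing-window harness -------------------------------------------------

# Aggregate a raw measurement table (one row per replicate, value possibly
# qualified, optional `excluded` flag) into per-compound records.
prepare_records <- function(measurements, sigma_exp) {
  if ("excluded" %in% names(measurements)) {
    measurements <- measurements[!(as.integer(measurements$excluded) %in% 1L), ,
                                 drop = FALSE]
  }
  md <- build_measurement_distributions(measurements, sigma_exp)
  dates <- aggregate(list(date = as.Date(measurements$date)),
                     by = list(compound_id = measurements$compound_id),
                     FUN = min)
  out <- merge(md, dates, by = "compound_id", sort = FALSE)
  out[order(out$date, out$compound_id), , drop = FALSE]
}

#' Run the temporal growing-window protocol
#'
#' Reproduces the full experimental protocol on a compound series:
#' \enumerate{
#'   \item Estimate `sigma_exp` from the QC table and build per-compound
#'     measurement distributions (qualified values stripped, flagged rows
#'     dropped).
#'   \item Split chronologically into initial training set,
#'     parameterization test set and monthly experimental test windows.
#'   \item Fit the model on the (reduced) initial training set, predict the
#'     parameterization set, and fit every requested error-estimation
#'     method's parameters (uniform RMSEs; `k` by mean-KL search;
#'     regression calibrations with the intercept pinned at `sigma_exp^2`).
#'     These parameters are then frozen.
#'   \item For each monthly window: fold all earlier data into the training
#'     set (reduced to `cap` compounds as `recent` newest + `random_n`
#'     random), retrain, and predict the window with every PD method using
#'     the frozen error parameters over a freshly rebuilt data context.
#'   \item Pool the monthly predictions and evaluate each method: mean KL,
#'     estimated-vs-observed RMSE bins, and per-bin KL differences against
#'     the uniform TS baseline.
#' }
#'
#' @param measurements data frame: `compound_id`, `date` (ISO-8601),
#'   `value` (string, possibly qualified), optional `excluded` (0/1).
#' @param descriptors numeric matrix with rownames = compound ids.
#' @param qc QC replicate table (`compound_id`, `value`), or `NULL` when
#'   `sigma_exp` is supplied directly.
#' @param spec a [regressor_spec()] for the point-prediction model.
#' @param error_methods subset of
#'   `c("TS","CV","D2M-EUC","D2M-MD","LE-EUC","LE-MD","LEC-EUC","LEC-MD",
#'   "BV","BVC","EM")`.
#' @param param_start,test_start split dates (see [temporal_split()]).
#' @param sigma_exp assay error; estimated from `qc` when `NULL`.
#' @param k_grid candidate neighbour counts for [optimize_k()].
#' @param n_members bagged-ensemble size for BV/BVC (default 100).
#' @param outer_folds,inner_folds folds for [double_loop_cv()].
#' @param error_model_spec learner for the EM method's absolute-error model
#'   (default ridge).
#' @param cap,recent,random_n training-set reduction rule (see
#'   [reduce_training_set()]).
#' @param bin_size bin size for the pooled evaluation (default 200).
#' @param seed master seed; all stage seeds derive from it.
#' @return List with `sigma_exp`, `frozen` (per-method frozen parameters),
#'   `predictions` (long data frame: compound_id, month, method, mu_pred,
#'   sigma_pred, mu_obs, sigma_obs), `evaluation` (per-method mean KL and
#'   bin tables), and `counts` (per-month and combined test sizes).
#' @export
run_growing_window <- function(measurements, descriptors, qc = NULL,
                               spec = regressor_spec("ridge"),
                               error_methods = c("TS", "CV", "D2M-EUC", "BV"),
                               param_start, test_start, sigma_exp = NULL,
                               k_grid = c(1L, 2L, 3L, 5L, 8L, 12L, 20L, 50L,
                                          100L, 200L),
                               n_members = 100L, outer_folds = 7L,
                               inner_folds = 7L,
                               error_model_spec = regressor_spec("ridge"),
                               cap = 35000L, recent = 20000L,
                               random_n = 15000L, bin_size = 200L, seed = 1L) {
  bad <- setdiff(error_methods, c(uniform_kinds, variable_kinds))
  if (length(bad)) {
    stop("unknown error methods: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(sigma_exp)) {
    if (is.null(qc)) stop("supply `qc` or `sigma_exp`", call. = FALSE)
    sigma_exp <- experimental_error_from_qc(qc)
  }
  descriptors <- as.matrix(descriptors)
  if (is.null(rownames(descriptors))) {
    stop("`descriptors` must have compound ids as rownames", call. = FALSE)
  }

  records <- prepare_records(measurements, sigma_exp)
  records <- records[records$compound_id %in% rownames(descriptors), , drop = FALSE]
  split <- temporal_split(records$date, param_start, test_start)
  if (!length(split$train_idx) || !length(split$param_idx)) {
    stop("empty training or parameterization subset", call. = FALSE)
  }

  fam_of <- vapply(error_methods, method_family, character(1))
  needs_cv <- any(fam_of %in% c("CV", "LE", "LEC", "EM"))
  needs_bag <- any(fam_of %in% c("BV", "BVC"))

  # A training "context": reduced records, scaler, fitted model and the
  # auxiliary structures the requested methods need. Rebuilt every retrain.
  build_context <- function(rec, stage) {
    rec <- reduce_training_set(rec, cap, recent, random_n,
                               seed = stage_seed(seed, paste0("reduce-", stage)))
    X_raw <- descriptors[rec$compound_id, , drop = FALSE]
    scaler <- descriptor_scaler(X_raw)
    X <- apply_scaler(scaler, X_raw)
    y <- rec$mu_obs
    model <- fit_regressor(spec, X, y, inner_folds = inner_folds,
                           seed = stage_seed(seed, paste0("fit-", stage)))
    cv <- if (needs_cv) {
      double_loop_cv(spec, X, y, outer_folds = outer_folds,
                     inner_folds = inner_folds,
                     seed = stage_seed(seed, paste0("cv-", stage)))
    }
    ens <- if (needs_bag) {
      if (inherits(model, "qsar_model") && model$algorithm == "rf") {
        model$fit # a random forest is already a bagged ensemble of trees
      } else {
        fit_bagged(spec, X, y, n_members = n_members,
                   seed = stage_seed(seed, paste0("bag-", stage)),
                   inner_folds = inner_folds)
      }
    }
    em <- if (any(fam_of == "EM")) {
      fit_regressor(error_model_spec, X, cv$abs_error,
                    inner_folds = inner_folds,
                    seed = stage_seed(seed, paste0("em-", stage)))
    }
    list(records = rec, scaler = scaler, X = X, y = y, model = model,
         cv = cv, ensemble = ens, error_model = em)
  }

  # --- parameterization pass -------------------------------------------------
  ctx0 <- build_context(records[split$train_idx, , drop = FALSE], "init")
  param_rec <- records[split$param_idx, , drop = FALSE]
  Xp <- apply_scaler(ctx0$scaler, descriptors[param_rec$compound_id, , drop = FALSE])
  mu_param <- predict(ctx0$model, Xp)
  obs_param <- gaussian_dist(param_rec$mu_obs, param_rec$sigma_obs)
  res_param <- param_rec$mu_obs - mu_param

  frozen <- lapply(setNames(error_methods, error_methods), function(tag) {
    fam <- method_family(tag)
    metric <- method_metric(tag)
    whit <- if (metric == "mahalanobis") mahalanobis_whitener(ctx0$X)
    if (fam == "TS") {
      list(method = tag, uniform_rmse = rmse(res_param))
    } else if (fam == "CV") {
      list(method = tag, uniform_rmse = rmse(ctx0$cv$residual))
    } else if (fam == "D2M") {
      k <- optimize_k(k_grid, function(k) {
        s <- knn_mean_distance(Xp, ctx0$X, k, metric, whit)
        predict(fit_error_regression(s, res_param, sigma_exp), s)
      }, obs_param, mu_param, sigma_exp, n_train = nrow(ctx0$X))
      s <- knn_mean_distance(Xp, ctx0$X, k, metric, whit)
      list(method = tag, k = as.integer(k),
           calibration = fit_error_regression(s, res_param, sigma_exp))
    } else if (fam == "LE") {
      k <- optimize_k(k_grid, function(k) {
        local_error(Xp, ctx0$X, ctx0$cv, k, metric, whit)
      }, obs_param, mu_param, sigma_exp, n_train = nrow(ctx0$X))
      list(method = tag, k = as.integer(k))
    } else if (fam == "LEC") {
      k <- optimize_k(k_grid, function(k) {
        s <- local_error(Xp, ctx0$X, ctx0$cv, k, metric, whit)
        predict(fit_error_regression(s, res_param, sigma_exp), s)
      }, obs_param, mu_param, sigma_exp, n_train = nrow(ctx0$X))
      s <- local_error(Xp, ctx0$X, ctx0$cv, k, metric, whit)
      list(method = tag, k = as.integer(k),
           calibration = fit_error_regression(s, res_param, sigma_exp))
    } else if (fam == "BV") {
      list(method = tag)
    } else if (fam == "BVC") {
      s <- bagged_variance_score(ctx0$ensemble, Xp)
      list(method = tag,
           calibration = fit_error_regression(s, res_param, sigma_exp))
    } else { # EM
      list(method = tag)
    }
  })

  make_estimator <- function(fr, ctx) {
    if (fr$method %in% uniform_kinds) {
      new_error_estimator(fr$method, sigma_floor = sigma_exp,
                          uniform_rmse = fr$uniform_rmse)
    } else {
      make_variable_estimator(fr$method, sigma_floor = sigma_exp,
                              k = fr$k, calibration = fr$calibration,
                              train_X = ctx$X, cv_table = ctx$cv,
                              ensemble = ctx$ensemble,
                              error_model = ctx$error_model)
    }
  }

  # --- monthly growing-window predictions ------------------------------------
  preds <- list()
  month_keys <- names(split$months)
  for (mi in seq_along(month_keys)) {
    key <- month_keys[mi]
    idx <- split$months[[key]]
    if (!length(idx)) { warning("empty month ", key, "; skipped"); next }
    month_start <- as.Date(paste0(key, "-01"))
    train_rec <- records[records$date < month_start, , drop = FALSE]
    ctx <- build_context(train_rec, key)
    test_rec <- records[idx, , drop = FALSE]
    Xt <- apply_scaler(ctx$scaler,
                       descriptors[test_rec$compound_id, , drop = FALSE])
    mu <- predict(ctx$model, Xt)
    for (tag in error_methods) {
      est <- make_estimator(frozen[[tag]], ctx)
      sig <- estimate_sigma(est, Xt)
      preds[[paste(key, tag)]] <- data.frame(
        compound_id = test_rec$compound_id, month = key, method = tag,
        mu_pred = mu, sigma_pred = sig, mu_obs = test_rec$mu_obs,
        sigma_obs = test_rec$sigma_obs, stringsAsFactors = FALSE)
    }
  }
  predictions <- do.call(rbind, c(preds, list(make.row.names = FALSE)))

  # --- pooled evaluation -----------------------------------------------------
  evaluation <- lapply(setNames(error_methods, error_methods), function(tag) {
    d <- predictions[predictions$method == tag, , drop = FALSE]
    pred <- gaussian_dist(d$mu_pred, d$sigma_pred)
    obs <- gaussian_dist(d$mu_obs, d$sigma_obs)
    out <- list(mean_kl = mean_kl(obs, pred),
                bins = bin_by_estimated_error(pred, obs,
                                              min(bin_size, length(pred))))
    if (tag != "TS" && "TS" %in% error_methods) {
      u <- predictions[predictions$method == "TS", , drop = FALSE]
      out$kl_diff <- kl_difference_profile(
        pred, gaussian_dist(u$mu_pred, u$sigma_pred), obs,
        min(bin_size, length(pred)))
    }
    out
  })

  month_n <- vapply(split$months, length, integer(1))
  counts <- data.frame(month = names(month_n), n = as.integer(month_n),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(sigma_exp = sigma_exp, frozen = frozen, predictions = predictions,
       evaluation = evaluation,
       counts = list(per_month = counts,
                     combined = combine_test_window_counts(counts)))
}
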