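test_that("qualified values parse with the symbol stripped but retained", {
  out <- parse_qualified_value(c(">5", "<-1.4", "3.2", "<=2", ">= 0.5"))
  expect_equal(out$value, c(5, -1.4, 3.2, 2, 0.5))
  expect_equal(out$qualifier, c(">", "<", "", "<=", ">="))
  expect_warning(bad <- parse_qualified_value(c("1", "about 5")), "could not parse")
  expect_true(is.na(bad$value[2]))
})

test_that("training-set reduction keeps the newest and samples the rest", {
  rec <- data.frame(id = 1:30000,
                    date = as.Date("2000-01-01") + seq_len(30000))
  expect_identical(reduce_training_set(rec), rec)
  big <- data.frame(id = 1:40000, date = as.Date("2000-01-01") + seq_len(40000))
  red <- reduce_training_set(big, seed = 5L)
  expect_equal(nrow(red), 35000L)
  expect_true(all(40000:20001 %in% red$id)) # all 20,000 newest retained
  red2 <- reduce_training_set(big, seed = 5L)
  expect_identical(red, red2)
  expect_error(reduce_training_set(big, cap = 1000L), "at least")
})

test_that("temporal splits are disjoint, exhaustive and chronological", {
  dates <- as.Date("2010-06-15") + seq(0, 720, by = 5)
  sp <- temporal_split(dates, "2011-01-01", "2011-07-01")
  all_idx <- c(sp$train_idx, sp$param_idx, unlist(sp$months))
  expect_setequal(all_idx, seq_along(dates))
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_true(all(dates[sp$train_idx] < as.Date("2011-01-01")))
  expect_true(all(dates[sp$param_idx] >= as.Date("2011-01-01") &
                    dates[sp$param_idx] < as.Date("2011-07-01")))
  expect_identical(names(sp$months), sort(names(sp$months)))
  expect_error(temporal_split(dates, "2011-07-01", "2011-01-01"), "precede")
})

test_that("combined window counts reproduce the benchmark bookkeeping", {
  counts <- example_monthly_counts()
  expect_equal(nrow(counts), 10L)
  totals <- combine_test_window_counts(counts)
  expect_equal(unname(totals["logd"]), 8108)
  expect_equal(unname(totals["hppb"]), 4792)
  expect_equal(unname(totals["caco2"]), 1470)
})

test_that("the growing-window harness is leak-free, frozen and deterministic", {
  ds <- small_series(seed = 21L)
  run <- function() {
    run_growing_window(
      ds$measurements, ds$descriptors, qc = ds$qc,
      spec = regressor_spec("ridge"),
      error_methods = c("TS", "CV", "D2M-EUC"),
      param_start = ds$param_start, test_start = ds$test_start,
      k_grid = c(1L, 3L, 8L, 20L), bin_size = 50L, seed = 3L)
  }
  res <- run()
  # every test month predicted once per method, no compound in two months
  preds <- res$predictions
  expect_setequal(unique(preds$method), c("TS", "CV", "D2M-EUC"))
  per_method <- split(preds, preds$method)
  for (d in per_method) expect_equal(anyDuplicated(d$compound_id), 0L)
  # test compounds all postdate the parameterization window
  truth <- ds$truth
  test_ids <- unique(preds$compound_id)
  expect_true(all(as.Date(truth$date[match(test_ids, truth$compound_id)]) >=
                    ds$test_start))
  # frozen parameters and predictions identical across reruns
  res2 <- run()
  expect_identical(res$frozen, res2$frozen)
  expect_identical(res$predictions, res2$predictions)
  # bookkeeping: combined count equals the sum over months
  expect_equal(unname(res$counts$combined["n"]),
               sum(res$counts$per_month$n))
  expect_equal(sum(res$counts$per_month$n), nrow(per_method[[1]]))
})

test_that("on drifting data the CV error estimate undershoots, TS is closer", {
  ds <- small_series(seed = 22L, n_per_month = 80L)
  res <- run_growing_window(
    ds$measurements, ds$descriptors, qc = ds$qc,
    spec = regressor_spec("ridge"), error_methods = c("TS", "CV"),
    param_start = ds$param_start, test_start = ds$test_start,
    bin_size = 50L, seed = 4L)
  d <- res$predictions[res$predictions$method == "TS", ]
  obs_rmse <- sqrt(mean((d$mu_obs - d$mu_pred)^2))
  ts_est <- res$frozen$TS$uniform_rmse
  cv_est <- res$frozen$CV$uniform_rmse
  expect_lt(cv_est, obs_rmse)
  expect_lt(abs(ts_est - obs_rmse), abs(cv_est - obs_rmse))
})
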