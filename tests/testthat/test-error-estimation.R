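test_that("distance functions match their definitions", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(1:4, 1:4), 0)
  expect_equal(euclidean_distance(c(2, 1), c(4, 5)),
               euclidean_distance(c(1, 2), c(5, 4))) # coordinate permutation
  expect_error(euclidean_distance(1:2, 1:3), "equal length")
})

test_that("Mahalanobis distance reduces to Euclidean under identity covariance", {
  set.seed(11)
  X <- matrix(rnorm(200 * 3), ncol = 3)
  # whiten so the sample covariance is exactly the identity
  Xw <- X %*% solve(chol(cov(X)))
  a <- c(1, -2, 0.5); b <- c(0, 0, 1)
  expect_equal(mahalanobis_distance(a, b, Xw), euclidean_distance(a, b),
               tolerance = 1e-8)
  expect_equal(mahalanobis_distance(a, a, Xw), 0)
})

test_that("rank-deficient training data takes the pseudo-inverse path", {
  set.seed(12)
  X <- matrix(rnorm(50 * 2), ncol = 2)
  X <- cbind(X, X[, 1]) # duplicated column: singular covariance
  d <- mahalanobis_distance(c(1, 0, 1), c(0, 0, 0), X)
  expect_true(is.finite(d))
  expect_gt(d, 0)
  expect_error(mahalanobis_distance(1:2, 2:3, matrix(1, 1, 2)), ">= 2 rows")
})

test_that("k-NN mean distance averages the k smallest with index tie-break", {
  train <- matrix(c(1, 2, 3), ncol = 1)
  expect_equal(knn_mean_distance(matrix(1), train, 1), 0)
  expect_equal(knn_mean_distance(matrix(0), train, 2), 1.5)
  expect_equal(knn_mean_distance(matrix(0), train, 3), 2)
  expect_error(knn_mean_distance(matrix(0), train, 4), "between 1 and")
})

test_that("local error is the CV RMSE of the nearest neighbours", {
  train <- matrix(c(0, 1, 2), ncol = 1)
  cvt <- data.frame(index = 1:3, fold = 1, observed = 0, prediction = 0,
                    residual = c(-0.3, 0.4, 0), abs_error = c(0.3, 0.4, 0))
  expect_equal(local_error(matrix(0), train, cvt, 1), 0.3)
  expect_equal(local_error(matrix(0.4), train, cvt, 2), sqrt(0.125))
  cvt0 <- cvt; cvt0$residual <- 0
  expect_equal(local_error(matrix(5), train, cvt0, 3), 0)
})

test_that("error regression pins the intercept and recovers a known slope", {
  expect_error(fit_error_regression(rep(0, 20), rnorm(20), 0.2), "undefined")
  expect_error(fit_error_regression(1:5, rnorm(5), 0.2), "at least 10")
  set.seed(13)
  s <- runif(5000, 0, 10)
  r <- rnorm(5000, 0, sqrt(0.037 * s + 0.04))
  cal <- fit_error_regression(s, r, sigma_exp = 0.2)
  expect_equal(cal$intercept, 0.04)
  expect_lt(abs(cal$slope - 0.037), 0.005)
  expect_equal(predict(cal, 0), 0.2) # sigma_exp at zero distance
  expect_true(all(diff(predict(cal, seq(0, 10, 1))) >= 0))
  # homoscedastic residuals: slope estimator centred at zero, clamped
  r0 <- rnorm(5000, 0, 0.2)
  cal0 <- fit_error_regression(s, r0, 0.2)
  expect_gte(cal0$slope, 0)
  expect_lt(cal0$slope, 0.003)
})

test_that("the moving-RMSE overlay tracks the fitted calibration curve", {
  set.seed(20)
  s <- runif(2000, 0, 10)
  r <- rnorm(2000, 0, sqrt(0.037 * s + 0.04))
  mv <- moving_rmse(s, r, block = 50L)
  expect_equal(nrow(mv), 40L)
  expect_true(all(diff(mv$mean_score) > 0))
  cal <- fit_error_regression(s, r, 0.2)
  # smoothed empirical curve hugs the fitted line
  expect_lt(median(abs(mv$rmse - predict(cal, mv$mean_score))), 0.08)
})

test_that("uniform estimators emit the validation RMSE everywhere", {
  est <- make_uniform_estimator("TS", residuals = c(1, 1))
  expect_equal(estimate_sigma(est, n = 3L), rep(1, 3))
  expect_equal(make_uniform_estimator("CV", residuals = c(0, 2))$uniform_rmse,
               sqrt(2))
  expect_equal(make_uniform_estimator("TS", residuals = -0.7)$uniform_rmse, 0.7)
  expect_error(make_uniform_estimator("TS", residuals = numeric(0)),
               "no residuals")
  expect_error(make_uniform_estimator("TS"), "supply residuals")
})

test_that("variable estimators validate components and apply the floor", {
  expect_error(make_variable_estimator("D2M-EUC", sigma_floor = 0.2, k = 3L),
               "requires")
  expect_error(make_variable_estimator("nope", sigma_floor = 0.2), "unknown")
  # BV with an all-agreeing ensemble is floored up from zero
  est <- make_variable_estimator("BV", sigma_floor = 0.21,
                                 ensemble = toy_ensemble(c(1, 1, 1)))
  expect_equal(estimate_sigma(est, matrix(0)), 0.21)
  # D2M with the reference calibration at score 1: sqrt(0.037 + 0.04)
  cal <- structure(list(slope = 0.037, intercept = 0.04, n = 10L),
                   class = "error_calibration")
  train <- matrix(c(0, 2), ncol = 1)
  est2 <- make_variable_estimator("D2M-EUC", sigma_floor = 0.1, k = 1L,
                                  calibration = cal, train_X = train)
  expect_equal(estimate_sigma(est2, matrix(1)), sqrt(0.077))
  # LE with k = 1 returns the neighbour's absolute residual
  cvt <- data.frame(index = 1:2, fold = 1, observed = 0, prediction = 0,
                    residual = c(0.5, -2), abs_error = c(0.5, 2))
  est3 <- make_variable_estimator("LE-EUC", sigma_floor = 0.1, k = 1L,
                                  train_X = train, cv_table = cvt)
  expect_equal(estimate_sigma(est3, matrix(0)), 0.5)
})

test_that("every method's emitted sigma dominates the floor", {
  set.seed(14)
  train <- matrix(rnorm(60 * 2), ncol = 2)
  y <- rnorm(60, 0, 0.05) # tiny errors so raw scores fall below the floor
  cvt <- double_loop_cv(regressor_spec("mean"), train, y, outer_folds = 5L,
                        seed = 1L)
  ens <- fit_bagged(regressor_spec("mean"), train, y, n_members = 10L, seed = 1L)
  em <- fit_regressor(regressor_spec("ridge"), train, cvt$abs_error)
  cal <- fit_error_regression(knn_mean_distance(train, train, 3L),
                              cvt$residual, 0.3)
  floor <- 0.3
  q <- matrix(rnorm(20 * 2), ncol = 2)
  ests <- list(
    make_uniform_estimator("TS", residuals = y, sigma_floor = floor),
    make_variable_estimator("D2M-EUC", floor, k = 3L, calibration = cal,
                            train_X = train),
    make_variable_estimator("D2M-MD", floor, k = 3L, calibration = cal,
                            train_X = train),
    make_variable_estimator("LE-EUC", floor, k = 5L, train_X = train,
                            cv_table = cvt),
    make_variable_estimator("LEC-MD", floor, k = 5L, train_X = train,
                            cv_table = cvt, calibration = cal),
    make_variable_estimator("BV", floor, ensemble = ens),
    make_variable_estimator("BVC", floor, ensemble = ens, calibration = cal),
    make_variable_estimator("EM", floor, error_model = em))
  for (e in ests) {
    expect_true(all(estimate_sigma(e, q) >= floor), info = e$method)
  }
})

test_that("k selection minimises mean KL, breaks ties low, and finds local signal", {
  obs <- gaussian_dist(rnorm(50), 0.2)
  expect_equal(as.integer(optimize_k(7L, function(k) rep(0.5, 50), obs,
                                     rep(0, 50), 0.2, n_train = 100)), 7L)
  # identical sigma for every k: the smallest candidate wins
  expect_equal(as.integer(optimize_k(c(3L, 9L), function(k) rep(0.5, 50), obs,
                                     rep(0, 50), 0.2, n_train = 100)), 3L)
  expect_error(optimize_k(c(500L, 900L), function(k) rep(0.5, 50), obs,
                          rep(0, 50), 0.2, n_train = 100), "no feasible")
  # dense-core/sparse-halo training cloud with noise tied to the 1-NN
  # distance: a small neighbour count should be selected
  Xtr <- cluster_cloud()
  Xp <- with_seed_test(43L, matrix(rnorm(2 * 400, 0, 3), ncol = 2))
  d1 <- knn_mean_distance(Xp, Xtr, 1L)
  res <- with_seed_test(44L, rnorm(400, 0, sqrt(0.5 * d1 + 0.04)))
  obs <- gaussian_dist(res, 0.2)
  k <- optimize_k(c(1L, 2L, 3L, 5L, 8L, 12L, 20L, 50L, 100L, 200L),
                  function(k) {
                    s <- knn_mean_distance(Xp, Xtr, k)
                    predict(fit_error_regression(s, res, 0.2), s)
                  }, obs, rep(0, 400), 0.2, n_train = nrow(Xtr))
  expect_lte(as.integer(k), 5L)
})

test_that("estimator state survives a JSON round trip", {
  cal <- structure(list(slope = 0.037, intercept = 0.04, n = 451L),
                   class = "error_calibration")
  est <- make_variable_estimator("D2M-EUC", sigma_floor = 0.21, k = 3L,
                                 calibration = cal,
                                 train_X = matrix(rnorm(10), ncol = 1))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  serialize_estimator(est, path)
  back <- deserialize_estimator(path)
  expect_equal(back$method, "D2M-EUC")
  expect_equal(back$k, 3L)
  expect_equal(back$calibration$slope, 0.037)
  expect_equal(back$sigma_floor, 0.21)
  # context is rebuilt, frozen parameters untouched
  back <- refresh_estimator(back, train_X = est$train_X)
  expect_equal(estimate_sigma(back, matrix(0.5)),
               estimate_sigma(est, matrix(0.5)))
})
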