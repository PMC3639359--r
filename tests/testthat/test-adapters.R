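test_that("baseline adapters honour the contract", {
  X <- matrix(c(0, 10), ncol = 1)
  m <- fit_regressor(regressor_spec("knn", params = list(k = 1L)), X, c(0, 10))
  expect_equal(predict(m, matrix(1)), 0) # nearest neighbour wins
  mm <- fit_regressor(regressor_spec("mean"), matrix(1:3, ncol = 1), c(1, 2, 3))
  expect_equal(predict(mm, matrix(c(-5, 100), ncol = 1)), c(2, 2))
  expect_warning(fit_regressor(regressor_spec("mean"), X, c(1, 1)), "constant")
  expect_error(regressor_spec("no-such-learner"), "unknown algorithm")
})

test_that("ridge adapter recovers a linear signal and refits deterministically", {
  set.seed(4)
  X <- matrix(rnorm(200 * 5), ncol = 5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3))
  spec <- regressor_spec("ridge", params = list(lambda = 1e-6))
  m1 <- fit_regressor(spec, X, y, seed = 9L)
  m2 <- fit_regressor(spec, X, y, seed = 9L)
  Xq <- matrix(rnorm(10 * 5), ncol = 5)
  expect_identical(predict(m1, Xq), predict(m2, Xq))
  expect_lt(max(abs(predict(m1, Xq) - drop(Xq %*% c(1, -2, 0.5, 0, 3)))), 1e-4)
})

test_that("grid tuning picks the better hyperparameter on clean data", {
  set.seed(5)
  X <- matrix(rnorm(120 * 3), ncol = 3)
  y <- drop(X %*% c(2, -1, 1))
  spec <- regressor_spec("ridge", tune = list(lambda = c(1e-6, 1e3)))
  m <- fit_regressor(spec, X, y, seed = 1L)
  expect_equal(m$params$lambda, 1e-6) # heavy shrinkage would wreck the fit
})

test_that("bagged ensembles expose mean prediction and member spread", {
  set.seed(6)
  X <- matrix(rnorm(40), ncol = 2)
  expect_error(fit_bagged(regressor_spec("mean"), X, rnorm(20), n_members = 1L),
               ">= 2")
  ens <- suppressWarnings(
    fit_bagged(regressor_spec("mean"), X, rep(2, 20), n_members = 10L, seed = 3L))
  expect_equal(unname(predict(ens, X[1:3, ])), rep(2, 3))
  expect_equal(unname(bagged_variance_score(ens, X[1:3, ])), rep(0, 3))
  ens2 <- suppressWarnings(
    fit_bagged(regressor_spec("mean"), X, rep(2, 20), n_members = 10L, seed = 3L))
  expect_identical(lapply(ens$members, `[[`, "idx"),
                   lapply(ens2$members, `[[`, "idx"))
  # spread is the sample standard deviation over members
  expect_equal(unname(bagged_variance_score(toy_ensemble(c(0, 2)), matrix(0))),
               sd(c(0, 2)))
})

test_that("ensemble spread is larger between training clusters than inside", {
  # two clusters whose frontier points sit almost equidistant from the
  # midpoint: bootstrap resamples that drop a frontier point flip the 1-NN
  # prediction across clusters, so the member spread peaks between clusters
  X <- matrix(c(-5, -5.05, -1.05, 5, 5.05, 1.0), ncol = 1)
  y <- c(-5, -5, -5, 5, 5, 5)
  ens <- fit_bagged(regressor_spec("knn", params = list(k = 1L)), X, y,
                    n_members = 40L, seed = 2L)
  inside <- bagged_variance_score(ens, matrix(-5))
  between <- bagged_variance_score(ens, matrix(0))
  expect_gt(between, inside)
  expect_gt(between, 1)
})

test_that("double-loop CV partitions cleanly and estimates the error honestly", {
  set.seed(8)
  X <- matrix(rnorm(70 * 2), ncol = 2)
  y <- rnorm(70, 0, 2)
  cv <- double_loop_cv(regressor_spec("mean"), X, y, outer_folds = 7L, seed = 5L)
  expect_setequal(cv$index, 1:70)
  expect_equal(anyDuplicated(cv$index), 0L)
  # mean predictor: CV RMSE estimates sd(y) up to fold-size correction
  expect_lt(abs(sqrt(mean(cv$residual^2)) - sd(y)), 0.35)
  cv2 <- double_loop_cv(regressor_spec("mean"), X, y, outer_folds = 7L, seed = 5L)
  expect_identical(cv$fold, cv2$fold)
  expect_error(double_loop_cv(regressor_spec("mean"), X, y, outer_folds = 1L),
               ">= 2")
})

test_that("a compound's own response never leaks into its out-of-fold prediction", {
  set.seed(9)
  X <- matrix(rnorm(60 * 2), ncol = 2)
  y <- rnorm(60)
  spec <- regressor_spec("knn", params = list(k = 3L))
  cv1 <- double_loop_cv(spec, X, y, outer_folds = 5L, seed = 11L)
  y2 <- y; y2[17] <- y2[17] + 1000
  cv2 <- double_loop_cv(spec, X, y2, outer_folds = 5L, seed = 11L)
  expect_identical(cv1$prediction[17], cv2$prediction[17])
})

test_that("descriptor scaler standardises with training statistics", {
  set.seed(10)
  X <- cbind(rnorm(50, 10, 3), rnorm(50, -2, 0.5), rep(7, 50))
  sc <- descriptor_scaler(X)
  Z <- apply_scaler(sc, X)
  expect_equal(ncol(Z), 2L) # zero-variance descriptor dropped
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(apply_scaler(sc, matrix(1, 1, 5)), "does not match")
})
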