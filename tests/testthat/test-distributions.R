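test_that("gaussian_dist enforces its invariants", {
  expect_error(gaussian_dist(0, 0), "strictly positive")
  expect_error(gaussian_dist(0, -1), "strictly positive")
  expect_error(gaussian_dist(Inf, 1), "finite")
  expect_error(gaussian_dist(NA_real_, 1), "finite")
  g <- gaussian_dist(c(1, 2), 0.5) # sigma recycled
  expect_length(g, 2L)
  expect_equal(g$sigma, c(0.5, 0.5))
  expect_equal(as.data.frame(g), data.frame(mu = c(1, 2), sigma = 0.5))
})

test_that("closed-form KL matches hand-derived and quadrature values", {
  p <- gaussian_dist(0, 1)
  expect_identical(kl_gaussian(p, p), 0)
  # frozen from trapezoid quadrature of the defining integral
  expect_equal(kl_gaussian(p, gaussian_dist(2.5, 3.0)), 1.0014, tolerance = 1e-4)
  expect_equal(kl_gaussian(p, gaussian_dist(2.5, 1.5)), 1.5166, tolerance = 1e-4)
})

test_that("worked example: wide honest errors beat tight overconfident ones", {
  ex <- make_worked_example()
  kl <- kl_gaussian(ex$observed, ex$predicted)
  names(kl) <- ex$labels
  # residuals: Q2 most accurate, yet Q3 earns the lowest divergence
  residuals <- abs(ex$observed$mu - ex$predicted$mu)
  expect_equal(unname(residuals), c(2.5, 2.0, 2.5))
  expect_lt(kl[["Q3"]], kl[["Q2"]])
  expect_lt(kl[["Q2"]], kl[["Q1"]])
})

test_that("quadrature oracle agrees with the closed form and converges", {
  p <- gaussian_dist(0, 1)
  q <- gaussian_dist(2.5, 1.5)
  expect_equal(kl_numeric(p, p), 0, tolerance = 1e-9)
  expect_equal(kl_numeric(p, q), kl_gaussian(p, q), tolerance = 1e-6)
  # trapezoid error is spectrally small for Gaussian-tailed integrands, so
  # refining the grid can only keep or shrink the (already machine-level) gap
  coarse <- abs(kl_numeric(p, q, n_points = 2001L) - kl_gaussian(p, q))
  fine <- abs(kl_numeric(p, q, n_points = 4001L) - kl_gaussian(p, q))
  expect_lte(fine, coarse)
  expect_lt(fine, 1e-9)
  expect_error(kl_numeric(p, q, n_points = 100L), "1000")
})

test_that("closed form tracks quadrature within 1e-6 on random pairs", {
  set.seed(1)
  for (i in 1:100) {
    p <- gaussian_dist(runif(1, -5, 5), runif(1, 0.1, 5))
    q <- gaussian_dist(runif(1, -5, 5), runif(1, 0.1, 5))
    expect_lt(abs(kl_gaussian(p, q) - kl_numeric(p, q)), 1e-6)
  }
})

test_that("KL is nonnegative, identifies equality, and is monotone in mean gap", {
  set.seed(2)
  for (i in 1:50) {
    p <- gaussian_dist(runif(1, -5, 5), runif(1, 0.1, 5))
    q <- gaussian_dist(runif(1, -5, 5), runif(1, 0.1, 5))
    expect_gte(kl_gaussian(p, q), 0)
    expect_identical(kl_gaussian(p, p), 0)
  }
  p <- gaussian_dist(0.3, 1.2)
  gaps <- seq(0, 4, by = 0.5)
  kl <- kl_gaussian(p, gaussian_dist(p$mu + gaps, 0.8))
  expect_true(all(diff(kl) > 0))
  # mean-term separability at fixed sigma
  sig <- 0.7; m1 <- 1.1; m2 <- -2.3
  d <- kl_gaussian(p, gaussian_dist(m1, sig)) - kl_gaussian(p, gaussian_dist(m2, sig))
  expect_equal(d, ((p$mu - m1)^2 - (p$mu - m2)^2) / (2 * sig^2))
})

test_that("mean_kl averages pairs and ignores pair order", {
  obs <- gaussian_dist(c(0, 0), 1)
  pred <- gaussian_dist(c(1, 2), 1)
  kl <- kl_gaussian(obs, pred)
  expect_equal(mean_kl(obs, pred), mean(kl))
  expect_equal(mean_kl(dist_pair_set(obs, pred)), mean(kl))
  expect_equal(mean_kl(obs[2:1], pred[2:1]), mean_kl(obs, pred))
  expect_equal(mean_kl(obs, obs), 0)
  expect_error(dist_pair_set(obs, gaussian_dist(1, 1)), "equal length")
})

test_that("sigma floor replaces too-small prediction errors only", {
  expect_equal(apply_sigma_floor(0.05, 0.21), 0.21)
  expect_equal(apply_sigma_floor(0.50, 0.21), 0.50)
  expect_equal(apply_sigma_floor(0.21, 0.21), 0.21)
  expect_equal(apply_sigma_floor(c(0, 0.1, 1), 0.2), c(0.2, 0.2, 1))
  expect_error(apply_sigma_floor(0.1, -1), "positive")
  expect_error(apply_sigma_floor(-0.1, 0.2), "nonnegative")
})
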