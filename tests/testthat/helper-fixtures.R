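# Shared fixtures, built in code at test time.

# Small drifting synthetic series for harness-level tests.
small_series <- function(seed = 1L, n_per_month = 60L) {
  generate_synthetic(synthetic_config(
    n_per_month = n_per_month, n_months = 10L, n_train_months = 6L,
    n_param_months = 2L, n_descriptors = 8L, seed = seed))
}

# Two-cluster training set in 2-d: a dense core and a sparse halo, so local
# density (and hence nearest-neighbour distance) varies strongly.
cluster_cloud <- function(n_core = 300L, n_halo = 100L, seed = 42L) {
  with_seed_test(seed, rbind(
    matrix(rnorm(2 * n_core, 0, 0.5), ncol = 2),
    matrix(rnorm(2 * n_halo, 0, 4), ncol = 2)
  ))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Hand-built two-member ensemble of constant predictors, for spread
# semantics tests.
toy_ensemble <- function(mus) {
  structure(list(algorithm = "mean", params = list(),
                 members = lapply(mus, function(m) list(fit = list(mu = m)))),
            class = "bagged_ensemble")
}
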