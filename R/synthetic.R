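# Synthetic compound-series generator: temporally ordered descriptors with
# chemical-space drift, distance-dependent model difficulty, Gaussian
# measurement noise, replicate measurements and QC compounds.

#' Configuration for the synthetic compound-series generator
#'
#' The generator emulates the statistical structure the framework assumes:
#' compounds arrive in monthly batches whose descriptor distribution drifts
#' away from the initial chemical space (sequential exploration). The drift
#' is modulated per compound by an exponential exploration factor, so every
#' batch mixes compounds that extend well-charted series (factor near zero)
#' with compounds that leap into new descriptor territory (large factor) -
#' without this within-batch heterogeneity the distance to the training
#' cloud would concentrate tightly in high-dimensional descriptor space and
#' carry no usable reliability signal. The true
#' property is a linear latent function plus an irreducible difficulty
#' component whose variance grows with the Euclidean distance `d` from the
#' initial-month descriptor centroid (`Var = noise_slope * d`), which makes
#' distance-to-model error estimation favourable by construction; observed
#' replicates add i.i.d. Gaussian measurement noise `N(0, sigma_exp)`; and a
#' panel of QC compounds is measured repeatedly for assay-error estimation.
#'
#' Defaults give a desk-scale series: 28 months of 250 compounds (20 months
#' initial training, 4 parameterization, 4 test), 20 descriptors, drift of
#' 0.06 descriptor SD per month, difficulty slope 0.037 and single-shot
#' error 0.2 log units (so the difficulty regression has intercept
#' `sigma_exp^2 = 0.04`), a 20% chance of replicate measurement (2-3
#' replicates), and 5 QC compounds with 200 replicates each.
#'
#' @param n_per_month compounds per monthly batch.
#' @param n_months total number of months.
#' @param n_train_months months forming the initial training set.
#' @param n_param_months months forming the parameterization test set.
#' @param n_descriptors descriptor dimension.
#' @param drift mean shift of every descriptor per month, in descriptor-SD
#'   units (>= 0); each compound's shift is `drift * (month - 1)` times its
#'   own exploration factor, drawn from an exponential distribution with
#'   mean 1.
#' @param noise_slope slope of the difficulty variance in the distance from
#'   the initial centroid.
#' @param sigma_exp single-shot measurement error (> 0).
#' @param replicate_prob probability a compound is measured more than once.
#' @param max_replicates maximum replicate count.
#' @param qualifier_prob probability a reported value carries a `<`/`>`
#'   qualifier (value retained, symbol stripped downstream).
#' @param n_qc_compounds,qc_replicates QC panel size and replicates each.
#' @param seed integer seed; identical configs give identical datasets.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_month = 250L, n_months = 28L,
                             n_train_months = 20L, n_param_months = 4L,
                             n_descriptors = 20L, drift = 0.06,
                             noise_slope = 0.037, sigma_exp = 0.2,
                             replicate_prob = 0.2, max_replicates = 3L,
                             qualifier_prob = 0.02, n_qc_compounds = 5L,
                             qc_replicates = 200L, seed = 1L) {
  cfg <- list(n_per_month = as.integer(n_per_month),
              n_months = as.integer(n_months),
              n_train_months = as.integer(n_train_months),
              n_param_months = as.integer(n_param_months),
              n_descriptors = as.integer(n_descriptors), drift = drift,
              noise_slope = noise_slope, sigma_exp = sigma_exp,
              replicate_prob = replicate_prob,
              max_replicates = as.integer(max_replicates),
              qualifier_prob = qualifier_prob,
              n_qc_compounds = as.integer(n_qc_compounds),
              qc_replicates = as.integer(qc_replicates),
              seed = as.integer(seed))
  if (cfg$sigma_exp <= 0 || cfg$drift < 0 || cfg$noise_slope < 0) {
    stop("invalid config: sigma_exp must be > 0, drift and noise_slope >= 0",
         call. = FALSE)
  }
  if (cfg$n_train_months + cfg$n_param_months >= cfg$n_months) {
    stop("need at least one test month after training + parameterization",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic compound series
#'
#' @param config a [synthetic_config()].
#' @return List with:
#'   \describe{
#'     \item{measurements}{replicate table: `compound_id`, `date`, `value`
#'       (character, occasionally qualified), `assay`, `excluded`.}
#'     \item{descriptors}{numeric matrix, rownames = compound ids.}
#'     \item{qc}{QC replicate table: `compound_id`, `value`.}
#'     \item{truth}{ground-truth sidecar per compound: month, date, latent
#'       mean, difficulty draw, true value, distance to the initial
#'       centroid, replicate count and the implied `sigma_obs`.}
#'     \item{param_start, test_start}{split dates matching the config.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    p <- cfg$n_descriptors
    beta <- rnorm(p) / sqrt(p) # latent signal of roughly unit variance
    months <- seq(as.Date("2010-01-01"), by = "month",
                  length.out = cfg$n_months)
    n_total <- cfg$n_per_month * cfg$n_months
    ids <- sprintf("CMP%06d", seq_len(n_total))

    X <- matrix(NA_real_, n_total, p, dimnames = list(ids, paste0("d", 1:p)))
    month_of <- rep(seq_len(cfg$n_months), each = cfg$n_per_month)
    exploration <- stats::rexp(n_total) # per-compound leap into new space
    for (m in seq_len(cfg$n_months)) {
      rows <- which(month_of == m)
      shift <- cfg$drift * (m - 1) * exploration[rows]
      X[rows, ] <- matrix(rnorm(length(rows) * p), ncol = p) +
        matrix(shift, length(rows), p)
    }
    d_centroid <- sqrt(rowSums(X^2)) # initial-month descriptor mean is 0
    latent_mean <- drop(X %*% beta)
    difficulty <- rnorm(n_total, 0, sqrt(cfg$noise_slope * d_centroid))
    true_value <- latent_mean + difficulty

    n_rep <- ifelse(runif(n_total) < cfg$replicate_prob,
                    sample(2:max(cfg$max_replicates, 2L), n_total,
                           replace = TRUE),
                    1L)
    dates <- months[month_of] + sample(0:27, n_total, replace = TRUE)
    rep_rows <- rep(seq_len(n_total), n_rep)
    values <- true_value[rep_rows] + rnorm(length(rep_rows), 0, cfg$sigma_exp)
    value_str <- formatC(values, format = "g", digits = 8)
    qual <- runif(length(values)) < cfg$qualifier_prob
    value_str[qual] <- paste0(sample(c("<", ">"), sum(qual), replace = TRUE),
                              value_str[qual])
    measurements <- data.frame(
      compound_id = ids[rep_rows],
      date = as.character(dates[rep_rows]),
      value = value_str, assay = "synthetic", excluded = 0L,
      stringsAsFactors = FALSE)

    qc_ids <- sprintf("QC%03d", seq_len(cfg$n_qc_compounds))
    qc_levels <- rnorm(cfg$n_qc_compounds, 0, 1)
    qc <- data.frame(
      compound_id = rep(qc_ids, each = cfg$qc_replicates),
      value = rnorm(cfg$n_qc_compounds * cfg$qc_replicates,
                    rep(qc_levels, each = cfg$qc_replicates), cfg$sigma_exp),
      stringsAsFactors = FALSE)

    truth <- data.frame(
      compound_id = ids, month = month_of, date = as.character(dates),
      latent_mean = latent_mean, difficulty = difficulty,
      true_value = true_value, d_centroid = d_centroid,
      exploration = exploration,
      n_replicates = n_rep,
      sigma_obs = cfg$sigma_exp / sqrt(n_rep),
      stringsAsFactors = FALSE)

    list(measurements = measurements, descriptors = X, qc = qc,
         truth = truth,
         param_start = months[cfg$n_train_months + 1L],
         test_start = months[cfg$n_train_months + cfg$n_param_months + 1L],
         config = cfg)
  })
}

#' The packaged worked example of KL scoring
#'
#' Three candidate predictive distributions for a single measurement
#' `P = N(0, 1)`: `Q1 = N(2.5, 1.5)`, `Q2 = N(2.0, 1.5)` and
#' `Q3 = N(2.5, 3.0)`. Q2 is the most accurate point prediction (residual
#' 2.0 versus 2.5), but its error estimate is too tight to cover the range
#' of plausible measurement outcomes; Q3's wider distribution earns the
#' lowest KL divergence. Scoring distributions rewards honest error
#' estimates, not just accurate means.
#'
#' @return A [dist_pair_set()] of three pairs, labelled Q1-Q3, with the same
#'   observed distribution repeated.
#' @export
make_worked_example <- function() {
  dist_pair_set(
    observed = gaussian_dist(c(0, 0, 0), 1),
    predicted = gaussian_dist(c(2.5, 2.0, 2.5), c(1.5, 1.5, 3.0)),
    labels = c("Q1", "Q2", "Q3")
  )
}
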