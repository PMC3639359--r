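---
title: "Predictive distributions for QSAR models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive distributions for QSAR models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarpd)
```

## The model

`qsarpd` treats both sides of a QSAR validation exercise as Gaussian
probability distributions. An experimental result becomes a *measurement
distribution* N(μ_obs, σ_obs): μ_obs is the mean of the compound's
replicate measurements and σ_obs = σ_exp/√N, where σ_exp is the assay's
single-shot error and N the replicate count. σ_exp is pooled from
quality-control compounds — compounds assayed repeatedly to monitor
consistency — as the root-mean-square deviation of each QC compound's
values from its own mean, with the *total* number of measurements in the
denominator. This is maximum-likelihood pooling, slightly biased low for
small replicate counts (by the factor √((n−M)/n) for M QC compounds over n
measurements); with the replicate counts QC panels actually carry the bias
is negligible, and we accept it for simplicity of the estimator. QC
compounds measured only once carry no variance information and are
excluded from pooling. All non-QC compounds inherit the QC-derived σ_exp;
per-compound heteroscedastic measurement error is out of scope. Replicates
are pooled as measured — no day-normalisation is applied first.

A prediction becomes a *predictive distribution* N(μ_pred, σ_pred): μ_pred
from any point-prediction learner, σ_pred from an error-estimation method.
The pairing is a *PD method*, and the quality of a test set of PD
predictions is the mean Kullback–Leibler divergence against the
measurement distributions:

$$D_{KL}(P\|Q) = \ln\frac{\sigma_q}{\sigma_p}
  + \frac{\sigma_p^2 + (\mu_p-\mu_q)^2}{2\sigma_q^2} - \frac12 .$$

This closed form is validated in the test suite against trapezoid
quadrature of the defining integral $\int p \ln(p/q)\,dx$. Its two
minimisation properties — minimal in the mean when μ_q = μ_p and in the
spread when σ_q = σ_p — are what make the score useful: inaccurate,
overconfident and needlessly vague predictive distributions are all
penalised by the same number, so prediction accuracy and error-estimate
honesty stop being competing objectives.

Because the measurement distribution plays the role of the "true"
distribution, a model cannot meaningfully predict a measurement more
precisely than the assay can measure it. Every σ_pred is therefore floored
at σ_exp. The floor applies only to predictive distributions, never to
measurement distributions, and it is applied *before* any KL is computed.

## Error-estimation methods and their parameters

Two uniform methods provide null hypotheses: `TS` assigns every query the
RMSE observed on a held-out temporal parameterization test set, `CV` the
RMSE from double-loop cross-validation on the training set (the inner loop
tunes hyperparameters, so the outer residuals are unbiased by model
selection). Both are constants frozen at parameterization time.

The variable methods map a per-compound reliability index to σ_pred:

* **D2M** — mean distance to the k nearest training compounds (Euclidean
  or Mahalanobis on descriptors standardised with training-set statistics;
  the Mahalanobis covariance is inverted by SVD pseudo-inverse with a
  relative singular-value cutoff of 1e-8, so collinear descriptors are
  harmless).
* **LE** — RMSE of the cross-validated residuals of the k nearest
  training neighbours, used directly as σ_pred.
* **BV** — standard deviation of member predictions across a bagged
  ensemble of 100 bootstrap models (denominator B−1; a random forest's
  trees serve directly as the ensemble).
* **D2M / LEC / BVC calibration** — squared residuals on the
  parameterization set are regressed on the raw index with the intercept
  pinned at σ_exp², giving σ_pred(s) = √(m·s + σ_exp²) with the slope
  clamped at m ≥ 0 (so σ_pred is nondecreasing in the index and equals
  σ_exp at zero). The pinned-intercept least-squares slope is
  m = Σ sᵢ(rᵢ² − σ_exp²) / Σ sᵢ². LEC and BVC reuse this machinery
  verbatim with the local-error RMSE and the ensemble SD as abscissa — we
  use the SD, not the variance, for BVC; both are monotone so rankings are
  unaffected, only the slope value differs. The regression is fitted to
  per-compound squared residuals; the block moving-average RMSE is a
  plotting overlay, not the fitting target.
* **EM** — a second regression model (ridge by default) predicts the
  absolute CV error; its output is used directly as σ_pred with no
  half-normal √(π/2) correction (the simplest reading; the correction
  would be a constant factor absorbed by the floor and the KL comparison).
  Negative predictions are floored at σ_exp.

The neighbour count k is chosen by minimising the mean KL of the resulting
predictive distributions on the parameterization set, over the default
grid {1, 2, 3, 5, 8, 12, 20, 50, 100, 200}; ties go to the smallest k.
Mean KL is the selection criterion because it is the quantity the whole
framework optimises. After parameterization, all error parameters (m, c,
k, uniform RMSEs) are frozen; monthly retraining rebuilds the data context
(training matrix, CV table, ensemble) but never refits them, and the
uniform TS RMSE is deliberately not refreshed monthly.

Point-prediction learners enter through an adapter registry
(`register_adapter()`): the framework never depends on learner internals.
Built-in cheap deterministic learners (mean, ridge, triangular-kernel
k-NN) keep the test suite fast; adapters for `randomForest` (250 trees,
nodesize 1) and `e1071` radial SVMs (cost 2 — the cost is exposed as a
parameter since reasonable readings of the reference configuration differ)
register automatically when those packages are present. Bagged ensembles
tune hyperparameters once on the full training data and hold them fixed
across members.

## The temporal protocol

`run_growing_window()` mirrors how such models are used in practice: train
on everything before the parameterization window, parameterize the error
methods once on that window, then for each subsequent month fold all
earlier data into the training set, retrain (including hyperparameter
re-tuning — models are rebuilt, not patched), predict the month, and pool
all monthly predictions for evaluation. Training sets larger than 35,000
compounds are reduced to the 20,000 most recent plus a seeded random
15,000 of the remainder. Qualified measurements (">5") are used with the
symbol stripped; rows flagged as suspect are dropped. No training
timestamp ever reaches or passes the test-window start, which the tests
verify.

## Evaluation diagnostics

Predictions ranked by σ_pred are binned (default 200 per bin; a final
partial bin merges into its predecessor) and each bin's estimated RMSE —
the root mean *square* of the σ_pred values, since RMSE is an L2 object —
is compared with the observed residual RMSE under a 95% Faber interval,
half-width 1.96·RMSE·√(1/2n). The same binning yields per-bin mean-KL
differences against the uniform TS baseline: negative differences are
information gains, and on heteroscedastic data they concentrate in the
highest-σ_pred bins. Normalized errors (μ_obs − μ_pred)/σ_pred are checked
against N(0,1) with a one-sample Kolmogorov–Smirnov test; constant input
is degenerate (statistic near its maximum) and flagged as such.

Predictive distributions convert to target-profile hit probabilities with
the Gaussian CDF, multiplied across endpoints under an explicit
independence assumption (the endpoint models are separate; correlated
endpoints are out of scope). Calibration tables rank and bin compounds by
estimated probability; 95% intervals on observed hit fractions use the
central limit theorem and are flagged reliable only when a bin holds more
than 5 hits.

## The synthetic generator

`generate_synthetic()` produces the structure the framework assumes, so
every stage is testable without any proprietary data: monthly compound
batches whose descriptors drift from the initial chemical space, a linear
latent property, an irreducible difficulty component with variance
`noise_slope · d` in the Euclidean distance d from the initial-month
centroid, i.i.d. N(0, σ_exp) measurement noise with occasional replicates,
and a QC panel. Defaults: 28 months × 250 compounds (20 training, 4
parameterization, 4 test, i.e. 5,000 / 1,000 / 1,000), 20 descriptors,
drift 0.06 SD/month, slope 0.037, σ_exp 0.2 log units, 20% replicate
probability, 5 QC compounds × 200 replicates. The descriptor dimension is
20 rather than the hundreds a real descriptor package emits — enough to
make distances meaningful at desk scale.

Each compound's drift is scaled by its own exponential exploration factor.
This matters: with a common monthly shift, distances to the training cloud
concentrate tightly in high-dimensional descriptor space (a chi-
distribution effect) and carry no usable reliability signal, which is not
how project chemistry behaves — real batches mix compounds that extend
charted series with leaps into new territory. The generator is therefore
D2M-favourable *by construction* (difficulty is literally a function of
distance), which is what makes directional tests meaningful: passing them
shows the machinery extracts a signal that is present, not that D2M wins
on any real assay. Other features of real data the generator does not
emulate: discrete/categorical descriptors, activity cliffs,
stereochemistry-blind descriptor collisions, assay drift over time, and
non-Gaussian measurement error.

## Numerical choices and degenerate inputs

* KL quadrature oracle: trapezoid rule over ±12 combined SDs with 100,001
  points; for Gaussian-tailed integrands the trapezoid rule converges
  spectrally, so the oracle sits at machine precision against the closed
  form.
* Distances: k-NN ties break deterministically by ascending training-row
  index; zero-variance descriptors are dropped by the scaler.
* Regression clamp: homoscedastic data drives the fitted slope to ~0 and
  the clamp returns exactly σ_exp everywhere; all-zero scores are an
  error (slope undefined).
* Seeds: every stochastic stage (fold assignment, bootstrap resampling,
  training-set reduction, generation) derives a named sub-seed from one
  master seed, so whole-pipeline runs are bit-reproducible.
* Sampling tolerances in seeded tests are stated against the design's own
  sampling error; e.g. the QC pooling check (5 compounds × 200
  replicates) has SE σ/√(2n) ≈ 2.2% of σ, so its ±5% band is a ~2σ
  statement and a small fraction of seeds would fail it for a perfectly
  correct estimator.

## Problem sizes

The shipped tests and the acceptance script run the full protocol at
5,000 training / 1,000 parameterization / 1,000 test compounds with the
ridge learner, 100,000-draw coverage simulations, 5,000-point calibration
recoveries and 10,000-compound calibration tables — sizes chosen so the
whole suite completes in well under a minute while keeping sampling error
far inside every asserted tolerance.

## Known limitations

Gaussian predictive distributions only (no non-parametric forms); a
single σ_exp per assay; independence across profile endpoints; no
significance machinery for comparing PD methods beyond the descriptive
per-bin diagnostics; distance-based methods inherit the usual caveats of
descriptor-space geometry (a compound can be close in descriptors yet
chemically novel, as stereoisomer collisions illustrate).
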