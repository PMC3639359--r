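# qsarpd

Treating QSAR predictions as probability distributions, and scoring them
that way.

## The problem

A QSAR model that returns only a point estimate tells a project team
nothing about how far to trust it. `qsarpd` represents every prediction as
a Gaussian *predictive distribution* N(μ_pred, σ_pred) and every
experimental result as a *measurement distribution* N(μ_obs, σ_obs), where
σ_obs = σ_exp / √N is derived from the assay's single-shot error σ_exp
(pooled from quality-control replicates) and the replicate count N. A
*PD method* is the pairing of a point-prediction model (which supplies
μ_pred) with an error-estimation method (which supplies σ_pred).

Sets of predictive distributions are scored against the measurement
distributions with the mean Kullback–Leibler divergence,

    D_KL(P‖Q) = ln(σ_q/σ_p) + (σ_p² + (μ_p − μ_q)²) / (2 σ_q²) − 1/2
    KL_AVE    = (1/N) Σ D_KL(P_i‖Q_i)

so that accuracy of the predictions and honesty of the error estimates
become a single objective: the PD method with the lowest mean KL over a
common test set has maximised information. Because a model cannot predict
an experimental result more precisely than the measurement itself, every
σ_pred is floored at σ_exp.

Error-estimation methods implemented:

* **Uniform** — one σ_pred for all queries: `TS` (RMSE on a temporal
  parameterization test set) and `CV` (RMSE from double-loop
  cross-validation). These are the null hypotheses any smarter method must
  beat.
* **Variable** — compound-specific σ_pred from a reliability index:
  distance-to-model (`D2M-EUC`, `D2M-MD`), local error (`LE-*`), corrected
  local error (`LEC-*`), bagged variance (`BV`, `BVC`) and a second
  regression model of the absolute error (`EM`). The corrected methods map
  the raw index s to σ_pred(s) = √(m·s + σ_exp²), a linear regression of
  squared residuals on the index with the intercept pinned at σ_exp².

A temporal growing-window harness reproduces the realistic validation
protocol (train on the past, parameterize the error methods once on a
held-out quarter, freeze them, then retrain monthly and predict forward),
and predictive distributions convert directly into probabilities of
hitting single- or multi-objective target property profiles via the
Gaussian CDF.

Everything is testable without proprietary data through a synthetic
generator that emulates temporally drifting compound series with
distance-dependent difficulty, replicate measurements and QC compounds.

## A worked example

Three models predict a property whose measured value is 0.0 ± 1.0. Q2 is
the most accurate point prediction, but its error estimate is too tight;
Q3 pairs a worse point prediction with an honest error bar:

```r
library(qsarpd)
ex <- make_worked_example()
data.frame(model   = ex$labels,
           mu      = ex$predicted$mu,
           sigma   = ex$predicted$sigma,
           residual = abs(ex$observed$mu - ex$predicted$mu),
           kl      = kl_gaussian(ex$observed, ex$predicted))
#>   model  mu sigma residual       kl
#> 1    Q1 2.5   1.5      2.5 1.516576
#> 2    Q2 2.0   1.5      2.0 1.016576
#> 3    Q3 2.5   3.0      2.5 1.001390
```

Q3 wins despite the larger residual: its distribution actually covers the
range of plausible measurement outcomes. The same distributions convert to
decision-ready probabilities:

```r
hit_probability(gaussian_dist(0, 1), -1, 1)
#> [1] 0.6826895
```

A full pipeline on synthetic data:

```r
ds  <- generate_synthetic(synthetic_config(seed = 1))
res <- run_growing_window(ds$measurements, ds$descriptors, qc = ds$qc,
                          spec = regressor_spec("ridge"),
                          error_methods = c("TS", "CV", "D2M-EUC"),
                          param_start = ds$param_start,
                          test_start = ds$test_start, seed = 1)
sapply(res$evaluation, function(e) e$mean_kl)
#>       TS       CV  D2M-EUC
#> 1.244211 1.302493 1.194853
```

The distance-to-model method beats both uniform baselines, and
`res$evaluation[["D2M-EUC"]]$kl_diff` shows the information gain
concentrating in the bin with the highest estimated errors — exactly where
recognising unreliable predictions pays.

A command-line wrapper (`inst/cli/qsarpd.R`) exposes
`simulate | run | evaluate | profile | calibrate-errors` for shell use.

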