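# distlag

Distributed lag models and ARDL bounds cointegration testing for R.

## What problem does this solve?

Applied analysts — in epidemiology, climate science, agriculture and
econometrics alike — often need to regress one time series on the *current
and past* values of others: how do this month's and the previous months'
temperature anomalies relate to sea level, or past exposure to current
health outcomes? `distlag` provides the standard dynamic-regression toolbox
for that question:

* **Finite distributed lag models.**
  `Y_t = α + Σ_{s=0}^{q} β_s X_{t−s} + ε_t`, with arbitrary per-predictor
  lag removal (`finite_dlm()`).
* **Almon polynomial lags.** The weights β_s are restricted to a degree-`k`
  polynomial in the lag index via transformed regressors
  `z_{t,j} = Σ_s s^j x_{t−s}`; the original weights and their tests are
  recovered through `β = Sγ` (`poly_dlm()`).
* **Koyck geometric lags.** The infinite model with `β_s = βφ^s` is fitted
  in its transformed form `Y_t = δ₁ + δ₂Y_{t−1} + δ₃X_t + ν_t` by
  two-stage least squares (instrumenting `Y_{t−1}` with `X_{t−1}`), with
  weak-instrument and Wu–Hausman diagnostics and recovery of
  `α = δ₁/(1−δ₂)`, `φ = δ₂`, `β = δ₃` (`koyck_dlm()`).
* **ARDL models.**
  `Y_t = μ₀ + Σ_i Σ_{l=0}^{p_i} β_{li} X_{i,t−l} + Σ_{j=1}^{q} γ_j Y_{t−j} + e_t`
  with per-series lag removal (`ardl_dlm()`), plus recursive multi-step
  forecasting with Monte Carlo prediction intervals (`forecast()`).
* **ARDL bounds cointegration test** (Pesaran–Shin–Smith). The conditional
  error-correction model is built for any of the five deterministic-term
  cases, the F statistic on the lagged levels is compared against embedded
  asymptotic lower/upper bounds, and the derived error-correction model
  reports the long-run coefficients `−α_i/α₀` and adjustment speed
  (`ardl_bounds()`), with residual diagnostics and CUSUM / CUSUM-of-squares
  / MOSUM stability charts.
* **Fast lag-order selection.** An exhaustive grid search and a two-stage
  algorithm (stage 1: equal short-run orders; stage 2: per-predictor
  fine-tuning at the selected autoregressive order) over AIC, BIC, MASE or
  GMRAE (`bounds_order_search()`). For three predictors and maxima of 10
  the exhaustive search fits 13,310 candidate models; the two-stage scheme
  fits at most 1,441.
* **Accuracy measures** including the relative-absolute-error family:
  MAE, MSE, MPE, MAPE, sMAPE, MASE, MRAE, GMRAE, MBRAE and UMBRAE
  (`gof()`, `sort_score()`, `search_finite_order()`).
* **Signal significance testing.** A Monte Carlo test comparing the
  standard deviation of rolling correlations against matched-correlation
  white noise (`signal_test()`, `rolling_correlation()`,
  `sd_percentiles()`).
* **Seedable synthetic generators** for ARDL and cointegrated processes
  with known parameters (`simulate_ardl()`, `simulate_cointegrated()`),
  used throughout the test suite.

## Worked example

Simulate a cointegrated pair (long-run slope 2, adjustment −0.5) and run
the bounds test:

```r
library(distlag)
d  <- simulate_cointegrated(n = 400, long_run_slope = 2,
                            adjustment = -0.5, seed = 42)
ardl_bounds(Y ~ X, d, case = 3, p = 1, q = 1)
```

```
ARDL bounds cointegration test (case 3, k = 1)
F = 121.066 on 2 and 392 df

 level   I0   I1      decision
 0.100 4.04 4.78 cointegration
 0.050 4.94 5.73 cointegration
 0.025 5.77 6.68 cointegration
 0.010 6.84 7.84 cointegration

Error-correction coefficient: -0.5234 (p = <2e-16 )

Long-run coefficients:
      X
2.00316
```

The F statistic (121.07) far exceeds the upper critical bound at every
tabulated level, so the levels terms are jointly significant:
cointegration. The error-correction model recovers the simulated long-run
slope (2.003 against a truth of 2) and adjustment speed (−0.52 against
−0.5); the diagnostics table (printed below the decision) shows no residual
autocorrelation, heteroskedasticity or misspecification, as expected for a
correctly specified model.

Model comparison uses the accuracy battery:

```r
da <- simulate_ardl(sim_spec(n = 300, k = 1, p = 1, q = 1, seed = 7))
gof(ardl = ardl_dlm(Y ~ X1, da, p = 1, q = 1),
    dlm  = finite_dlm(Y ~ X1, da, q = 2))
```

```
       n       MAE       MPE      MAPE     sMAPE      MASE       MSE     MRAE
ardl 299 0.7623200 0.2016394 0.9559734 0.5319159 0.4969334 0.9343287 3.903381
dlm  298 0.9862591 0.5407133 1.3805254 0.6648627 0.6417952 1.5424185 4.449622
         GMRAE     MBRAE    UMBRAE
ardl 0.4676623 0.3603901 0.5634529
dlm  0.5991974 0.4150326 0.7094969
```

MASE below 1 means both models beat the naive random-walk benchmark; the
ARDL fit dominates on every measure here, as it nests the true
data-generating process.

A command-line driver covering the same functionality (subcommands
`fixtures`, `dlm`, `poly`, `koyck`, `ardl`, `forecast`, `gof`, `search`,
`bounds`, `signal`) lives at `inst/cli/distlag.R`; every run writes a
`manifest.json` so results are replayable.

## Documentation

See the methods vignette, `vignettes/distributed-lag-models.Rmd`, for the
models, conventions (sample alignment, information-criterion parameter
counting, accuracy-measure scales), algorithmic choices and known
limitations.
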