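---
title: "Distributed lag models and ARDL bounds testing with distlag"
author: "distlag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed lag models and ARDL bounds testing with distlag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distlag)
```

# The models

`distlag` fits dynamic regressions between a dependent series $Y_t$ and $k$
independent series $X_{ti}$, $t = 1,\dots,n$, observed at a common
frequency. All lags are whole observation steps; no calendar arithmetic is
performed.

**Finite distributed lag model** of order $q$:
$$Y_t = \alpha + \sum_{s=0}^{q} \beta_s X_{t-s} + \epsilon_t .$$
`finite_dlm()` accepts several predictors (each contributes lags
$0,\dots,q$) and a `remove` list naming lags to drop per predictor;
including 0 removes the contemporaneous term. Whatever is removed, the
effective sample is the contiguous tail of the data: the first $q$ rows are
dropped and $n_{\mathrm{eff}} = n - q$. Removals therefore change the
coefficient count but never the sample — this matches the convention of
mainstream dynamic-regression software, keeps designs aligned, and makes
residual degrees of freedom a pure function of the declared order and the
retained columns.

**Almon polynomial restriction.** With a single predictor, the lag weights
can be forced onto a degree-$k$ polynomial in the lag index,
$\beta_s = \sum_{j=0}^{k} \gamma_j s^j$. Substituting gives transformed
regressors $z_{t,j} = \sum_{s=0}^{q} s^j x_{t-s}$ and an ordinary
regression of $Y$ on $(1, z_0, \dots, z_k)$. The original weights are
recovered through the linear map $\beta = S\gamma$ with $S_{sj} = s^j$
(and $0^0 = 1$), their covariance through $S\,\mathrm{cov}(\gamma)\,S'$,
and their $t$ tests use the transformed regression's residual degrees of
freedom. Design choices: the basis uses raw powers (no orthogonalisation or
endpoint restrictions) — the simplest basis consistent with the polynomial
shape — with a condition-number warning when $q \cdot k$ is large; the
intercept is always included. When $k = q$ the restriction is vacuous and
the recovered $\beta$ equals the unrestricted finite-DLM estimate on the
same sample, a property the test suite checks to $10^{-8}$.

**Koyck geometric lag.** The infinite geometric model
$Y_t = \alpha + \beta(X_t + \phi X_{t-1} + \phi^2 X_{t-2} + \cdots) + \epsilon_t$
is estimated in its transformed finite form
$$Y_t = \delta_1 + \delta_2 Y_{t-1} + \delta_3 X_t + \nu_t,
\qquad \nu_t = \epsilon_t - \phi\,\epsilon_{t-1}.$$
Because $\nu_t$ contains $\epsilon_{t-1}$, it is correlated with $Y_{t-1}$
and least squares is inconsistent; `koyck_dlm()` uses two-stage least
squares. The instrument set is $(1, X_t, X_{t-1})$ — the minimal
just-identified choice that instruments $Y_{t-1}$ with $X_{t-1}$, which is
also the choice consistent with single-degree-of-freedom weak-instrument
diagnostics. Attached diagnostics: the first-stage $F$ of the excluded
instrument (identically the squared first-stage $t$), and the Wu–Hausman
endogeneity test in its auxiliary-regression form (structural OLS augmented
with the first-stage residual, $F$ on that coefficient). Both are
asymptotic, so a warning is raised below 50 effective observations.
$R^2$ and the residual standard error are computed from the *structural*
residuals $y - Z\hat\delta$ (not the second-stage projected residuals),
since those are the residuals of the model actually interpreted; the
reported Wald statistic is the joint $F$ that all non-intercept
coefficients vanish, using the 2SLS covariance. The geometric-form
parameters are recovered exactly from the unrounded estimates:
$\alpha = \delta_1/(1-\delta_2)$, $\phi = \delta_2$, $\beta = \delta_3$.

**ARDL($p_1,\dots,p_k$; $q$).**
$$Y_t = \mu_0 + \sum_{i=1}^{k}\sum_{l=0}^{p_i} \beta_{li} X_{i,t-l}
      + \sum_{j=1}^{q} \gamma_j Y_{t-j} + e_t .$$
`ardl_dlm()` takes a common or per-predictor `p`, an autoregressive order
`q`, and a `remove` list for both blocks. The effective sample drops
$\max(p_{\max}, q)$ leading rows — declared orders count towards alignment
even when their lags are removed, so the printed degrees of freedom are
reproducible from the call alone.

# Forecasting

`forecast()` iterates the fitted equation forward. Future predictor values
must be supplied (`x_new`, one row per predictor, $h$ columns); predictor
paths are never extrapolated. Response lags beyond the sample use the
model's own earlier forecasts. For removed response lags the *state* still
uses observed/predicted values — removal affects regressors, not the
recursion's bookkeeping.

Prediction intervals are Monte Carlo: `nSim` trajectories receive an iid
Gaussian shock at every step, and the shocks feed back through the lagged
response terms, so intervals widen with the horizon whenever the model is
autoregressive. The default shock variance is the *empirical variance of
the observed dependent series*. That is an unusually wide choice (the
residual variance is the textbook one) but it is the convention this
toolchain targets; `shock = "residual"` switches to residual-variance
intervals. Bounds are per-step empirical percentiles with linear
interpolation between order statistics; a fixed `seed` makes the output
bit-reproducible. Because the bounds are percentiles of *simulated* paths,
they are not forced to bracket the deterministic point path — only
`lower < upper` is guaranteed.

# Accuracy measures

`gof()` reports, per model over its aligned (actual, fitted) pairs: MAE,
MPE, MAPE, sMAPE, MASE, MSE, MRAE, GMRAE, and — when at least two models
are compared — MBRAE and UMBRAE. Conventions that matter:

* Percentage-type measures (MPE, MAPE, sMAPE) are on the **fraction
  scale**, not multiplied by 100.
* The benchmark for all relative measures is the in-sample one-step naive
  (random-walk) forecast, $e^*_t = y_t - y_{t-1}$.
* MASE divides the model's mean absolute error by the naive mean absolute
  error, both over the benchmark-aligned subsample, so the naive forecast
  itself scores exactly 1.
* MBRAE is the mean of the bounded relative error
  $\mathrm{BRAE}_t = |e_t| / (|e_t| + |e^*_t|) \in [0,1]$ and
  $\mathrm{UMBRAE} = \mathrm{MBRAE}/(1-\mathrm{MBRAE})$; equal model and
  benchmark errors give exactly $1/2$ and $1$. Under these definitions
  MBRAE cannot exceed 1 and UMBRAE cannot be negative.
* Undefined terms ($y_t = 0$ for percentage errors, $e^*_t = 0$ for
  ratios) are dropped, with the dropped count recorded in an attribute.

`search_finite_order()` scans lag lengths (and polynomial orders) and ranks
by MASE, AIC, BIC, GMRAE, MBRAE or adjusted $R^2$. All candidates are
fitted on the common effective sample implied by `q_max`: likelihood-based
criteria computed on samples of different sizes are not comparable, and the
sample-size effect is large enough to corrupt order selection noticeably.

# The ARDL bounds test

To test for a long-run (cointegrating) relation the ARDL model is
re-parameterised as the conditional error-correction model
$$\Delta Y_t = \mu_0 + \mu_1 t + \alpha_0 Y_{t-1}
  + \sum_{i=1}^{k}\alpha_i X_{i,t-1}
  + \sum_{i=1}^{q}\gamma_i \Delta Y_{t-i}
  + \sum_{j=1}^{k}\sum_{l=0}^{p_j} \beta_{j,l}\Delta X_{j,t-l} + e_t,$$
and the null of *no level relationship* is
$H_0: \alpha_0 = \alpha_1 = \cdots = \alpha_k = 0$. The F statistic is
computed by the restricted-versus-unrestricted residual-sum-of-squares
formula, refitting without the levels block. The five deterministic-term
cases follow the standard taxonomy (1: none; 2: restricted intercept; 3:
unrestricted intercept; 4: + restricted trend; 5: + unrestricted trend);
for the *restricted* cases 2 and 4 the deterministic term joins the null,
so the restriction count is $k+2$ rather than $k+1$ — that is what
"restricted" means, and the choice is definitional rather than tunable.

Because the regressors may be I(0), I(1) or mutually cointegrated, the
statistic is compared against two critical bounds: the lower bound $I_0$
(all regressors stationary) and the upper bound $I_1$ (all unit-root).
$F > I_1$ establishes cointegration, $F < I_0$ establishes its absence,
and anything between is inconclusive. The asymptotic bounds for
$k = 1,\dots,10$ at the 10/5/2.5/1% levels are embedded for all five
cases; the package verified its transcription by simulating the asymptotic
null distribution before freezing the tables. Small-sample bounds for
$30 \le n \le 80$ are not bundled — the lookup falls back to the
asymptotic rows with an explicit warning, never silently.

**Order convention.** `p` and `q` count the difference lags literally as
they appear in the conditional model above: `q` lagged response
differences and predictor-difference lags $0,\dots,p_j$. Output of
`bounds_order_search()` therefore slots straight into `ardl_bounds()`
(software that starts the short-run sums at 1 instead of 0 needs a "+1"
adjustment; this package does not).

**Error-correction model.** The long-run coefficients are
$\theta_i = -\hat\alpha_i/\hat\alpha_0$ — the standard sign convention for
the decomposition of the conditional model, under which the
error-correction term $EC_{t-1} = Y_{t-1} - \sum_i \theta_i X_{i,t-1}$
measures the deviation from equilibrium and its coefficient in the ECM is
the (negative) adjustment speed. A degenerate $\hat\alpha_0 \approx 0$ is
an error, not an NaN.

**Diagnostics.** Breusch–Godfrey (default lag order = series frequency,
configurable), Ljung–Box, Breusch–Pagan, Shapiro–Wilk (skipped with a
notice outside its 3–5000 validity range) and Ramsey RESET with powers 2–3
of the fitted values.

**Stability.** Recursive residuals are standardized one-step prediction
errors from expanding-window least squares, computed with rank-one
(Sherman–Morrison) updates and verified in the test suite against
per-step refits. Three charts are produced with crossing flags:

* **CUSUM** with the classical Brown–Durbin–Evans linear boundaries
  ($\lambda = 0.850/0.948/1.143$ at the 10/5/1% levels).
* **CUSUM of squares** with a Brownian-bridge asymptotic approximation for
  the boundary offset around the expectation line; this approximation is
  conservative in small samples, which we accept because the chart is used
  as a visual screen.
* **MOSUM** (default bandwidth 0.15 of the recursive-residual sample).
  There is no convenient closed form for the sup-norm critical value of
  overlapping moving sums, so the boundary is Monte-Carlo calibrated at
  fit time under the Gaussian null (1000 replications, internal fixed
  seed, caller's RNG state restored), making results reproducible without
  shipping a critical-value table.

Noise-free (exactly linear) data would standardize floating-point dust;
the recursive residuals are treated as exact zeros when their spread is
below $10^{-10}$ of the response scale, giving flat paths and no
crossings.

# Lag-order search

The exhaustive search over $(p_1,\dots,p_k) \in \{0..\texttt{max\_p}\}^k$,
$q \in \{1..\texttt{max\_q}\}$ fits
$(\texttt{max\_p}+1)^k \cdot \texttt{max\_q}$ conditional models. The
two-stage algorithm first assumes equal short-run orders and scans the
$(\texttt{max\_p}+1)\cdot\texttt{max\_q}$ grid of $(p, q)$; it then fixes
the selected $q^*$ and scans the $(p^*+1)^k$ per-predictor grid. For
$k = 3$ and maxima of 10 that is at most $110 + 1331 = 1441$ models
against 13,310 — about a tenth of the work — and the optimality gap is
small because stage 1 already lands near the optimum. Properties asserted
by the tests: the enumerated grid sizes match the closed forms exactly for
all $(k, \texttt{max\_p}, \texttt{max\_q})$ tried; the two-stage criterion
value can never beat the full-search optimum; and the median relative gap
on synthetic ARDL data is below 1% for AIC and BIC.

Two decisions the algorithm's description leaves open are resolved as
follows. The stage-1 short-run range is $\{0,\dots,\texttt{max\_p}\}$ and
the stage-2 grid is $\{0,\dots,p^*\}^k$ — the variants consistent with
the model-count arithmetic above. Candidates are compared on a *common*
effective sample (trimmed to the largest candidate's alignment), for the
same comparability reason as in `search_finite_order()`; ties break
towards parsimony (smallest total order, then smallest $q$, then
lexicographically), which keeps the search deterministic.

# Signal significance testing

Short series with trends or seasonality can make pure noise look like
signal. The test computes rolling Pearson correlations of the two series
for several window widths (trailing windows; the path index is the window
end) and summarises each path by its standard deviation. The null
distribution of that SD is simulated: $N$ pairs of Gaussian white-noise
series of the same length and the same overall correlation as the data
(lower-triangular transform of independent normals), each reduced to its
rolling-correlation SD. One-tailed limits at the $(1-\ell)$ and $\ell$
percentiles flag series whose rolling correlations vary significantly
more *or less* than matched noise. For plotting, the per-width paths are
averaged over the time points covered by every width and smoothed with a
running median (span 3 by default — the smallest odd span; the filter is
named by the method, its span is not, so the minimal choice is the
default), with a normal-theory confidence band for the mean of the
filtered path. Windows in which either series is constant yield undefined
correlations; they are recorded as `NA` and excluded from the SD.

Both directions of the flag are informative: independent white noise is
flagged at rate $\approx 2(1-\ell)$ (a property the test suite checks
within Monte Carlo bands), while a shared component that keeps every
window steadily correlated — a strong seasonal cycle, for instance —
pushes the SD *below* the lower limit.

# Synthetic data generators

`simulate_ardl()` draws exogenous AR(1) predictors and generates the
response by the ARDL recursion with Gaussian innovations;
`simulate_cointegrated()` draws a random-walk predictor and a response
that error-corrects towards `long_run_slope * X` at rate `adjustment`
(zero adjustment gives two independent random walks — the
no-cointegration null). Both are pure functions of their spec, including
the seed; burn-in (default 200, minimum 50) removes initialisation
effects, and autoregressive specs are stationarity-checked through the
companion-matrix spectral radius unless an integrated process is
explicitly requested. Exogeneity is enforced (no feedback from $Y$ to
$X$), so estimator-consistency checks in the test suite are valid.

What these generators emulate: linear dynamics, Gaussian innovations,
exact lag structure, unit roots and error correction. What they do not:
heavy tails, heteroskedasticity, structural breaks, seasonality,
measurement error, or feedback. Passing recovery and size/power tests on
this synthetic family therefore demonstrates correctness of the
estimators and test machinery under the models' own assumptions — not
robustness of the methods on messy real data.

# Numerical conventions

* **Alignment.** The first `max_lag` rows are dropped; no padding or
  imputation. Missing values inside the modelling window are an error —
  silent row deletion would break lag alignment.
* **Information criteria.** The Gaussian log-likelihood counts the error
  variance as one extra parameter, so `AIC()`/`BIC()` agree with
  mainstream linear-model summaries; consequently AIC < BIC whenever
  $n_{\mathrm{eff}} > e^2$.
* **R² without an intercept** uses the uncentred total sum of squares
  (values are then not comparable with intercept models, as usual in R).
* **Rank deficiency** raises an error naming the collinear columns.
* **Percentiles** everywhere use linear interpolation between order
  statistics (R's default quantile type).
* The test-suite problem sizes (e.g. 100–400 Monte Carlo replicates,
  samples of 300–2000) were chosen as the smallest sizes at which the
  binomial/Monte-Carlo bands in the assertions are comfortably narrower
  than the effects being checked.

# Limitations

* Polynomial and Koyck models accept a single predictor.
* Predictor paths are never forecast; `x_new` must be supplied.
* Small-sample bounds-test critical values are not bundled (asymptotic
  fallback with a warning); the t-bound test on $\alpha_0$ is not
  implemented.
* Seasonal lag operators, irregular spacing and missing-data handling are
  out of scope.
* The MOSUM boundary is simulation-calibrated rather than tabulated;
  levels other than those tabulated for CUSUM (10/5/1%) are rejected.
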