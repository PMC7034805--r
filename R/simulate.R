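#' Specification of a synthetic ARDL data-generating process
#'
#' Describes the DGP used by [simulate_ardl()]: `k` exogenous predictors,
#' each a Gaussian AR(1), and a response generated by the ARDL recursion
#' `Y_t = mu0 + sum_i sum_{l=0..p} beta[l+1, i] X_{i,t-l}
#'        + sum_{j=1..q} gamma[j] Y_{t-j} + e_t`
#' with iid Gaussian innovations. The autoregressive coefficients are
#' stationarity-checked (companion-matrix spectral radius below 1) unless
#' `integrated = TRUE`.
#'
#' @param n sample size after burn-in.
#' @param k number of predictors.
#' @param p predictor lag order (common to all predictors).
#' @param q autoregressive order of the response.
#' @param mu0 intercept (default 0.5).
#' @param beta `(p+1) x k` matrix of lag weights (default: weights decaying
#'   as `0.8^l` on every predictor).
#' @param gamma length-`q` vector of autoregressive coefficients (default
#'   `0.5 * 0.5^(j-1)` scaled to be stationary).
#' @param x_ar AR(1) coefficient of the predictors (default 0.5).
#' @param sd innovation standard deviation of the response (default 1).
#' @param x_sd innovation standard deviation of the predictors (default 1).
#' @param burn_in burn-in length discarded from the front (>= 50).
#' @param integrated allow a unit-root response recursion.
#' @param seed RNG seed (stored; every draw in [simulate_ardl()] uses it).
#' @return list of class `"sim_spec"`.
#' @export
sim_spec <- function(n, k = 1, p = 1, q = 1, mu0 = 0.5, beta = NULL,
                     gamma = NULL, x_ar = 0.5, sd = 1, x_sd = 1,
                     burn_in = 200, integrated = FALSE, seed = 1) {
  p <- check_count(p, "p"); q <- check_count(q, "q"); k <- check_count(k, "k")
  if (burn_in < 50) stop("burn_in must be at least 50", call. = FALSE)
  if (is.null(beta))
    beta <- matrix(rep(0.8^(0:p), k), nrow = p + 1L, ncol = k)
  beta <- matrix(beta, nrow = p + 1L, ncol = k)
  if (is.null(gamma)) gamma <- if (q > 0) 0.5 * 0.5^(seq_len(q) - 1) else numeric(0)
  if (length(gamma) != q) stop("gamma must have length q", call. = FALSE)
  if (q > 0) {
    comp <- matrix(0, q, q)
    comp[1, ] <- gamma
    if (q > 1) comp[cbind(2:q, 1:(q - 1))] <- 1
    rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
    if (rho >= 1 && !integrated)
      stop("explosive/unit-root autoregressive coefficients (spectral radius ",
           round(rho, 3), "); set integrated = TRUE if intended", call. = FALSE)
  }
  structure(list(n = n, k = k, p = p, q = q, mu0 = mu0, beta = beta,
                 gamma = gamma, x_ar = x_ar, sd = sd, x_sd = x_sd,
                 burn_in = burn_in, integrated = integrated, seed = seed),
            class = "sim_spec")
}

#' Simulate an ARDL dataset with known parameters
#'
#' @param spec a [sim_spec()].
#' @return A [ts_table()] with series `Y, X1, ..., Xk`; the spec is attached
#'   as attribute `"spec"`.
#' @examples
#' d <- simulate_ardl(sim_spec(n = 100, k = 1, p = 1, q = 1, seed = 1))
#' head(d$values)
#' @export
simulate_ardl <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  N <- spec$n + spec$burn_in
  X <- matrix(0, N, spec$k)
  for (i in seq_len(spec$k)) {
    e <- stats::rnorm(N, 0, spec$x_sd)
    for (t in 2:N) X[t, i] <- spec$x_ar * X[t - 1L, i] + e[t]
  }
  y <- numeric(N)
  e <- stats::rnorm(N, 0, spec$sd)
  start <- max(spec$p, spec$q) + 1L
  for (t in start:N) {
    val <- spec$mu0 + e[t]
    for (i in seq_len(spec$k))
      for (l in 0:spec$p) val <- val + spec$beta[l + 1L, i] * X[t - l, i]
    for (j in seq_len(spec$q)) val <- val + spec$gamma[j] * y[t - j]
    y[t] <- val
  }
  keep <- (spec$burn_in + 1L):N
  vals <- cbind(Y = y[keep], X[keep, , drop = FALSE])
  colnames(vals) <- c("Y", paste0("X", seq_len(spec$k)))
  out <- ts_table(vals, frequency = 1)
  attr(out, "spec") <- spec
  out
}

#' Simulate a cointegrated (or independent random-walk) pair
#'
#' `X` is a Gaussian random walk; `Y` adjusts towards the long-run relation
#' `long_run_slope * X` at rate `adjustment`:
#' `dY_t = adjustment * (Y_{t-1} - long_run_slope * X_{t-1}) + e_t`.
#' `adjustment = 0` yields two independent random walks — the
#' no-cointegration null.
#'
#' @param n sample size after burn-in.
#' @param long_run_slope equilibrium slope `b` in `Y ~ b X`.
#' @param adjustment error-correction speed, `-2 < adjustment <= 0`.
#' @param sd innovation standard deviation (both series).
#' @param burn_in burn-in length (default 200).
#' @param seed RNG seed.
#' @return A [ts_table()] with series `Y, X`.
#' @examples
#' d <- simulate_cointegrated(n = 300, long_run_slope = 2,
#'                            adjustment = -0.5, seed = 1)
#' @export
simulate_cointegrated <- function(n, long_run_slope = 1, adjustment = -0.5,
                                  sd = 1, burn_in = 200, seed = 1) {
  if (adjustment > 0 || adjustment <= -2)
    stop("adjustment must satisfy -2 < adjustment <= 0 (divergent otherwise)",
         call. = FALSE)
  if (burn_in < 50) stop("burn_in must be at least 50", call. = FALSE)
  set.seed(seed)
  N <- n + burn_in
  x <- cumsum(stats::rnorm(N, 0, sd))
  y <- numeric(N)
  ey <- stats::rnorm(N, 0, sd)
  if (adjustment == 0) {
    y <- cumsum(ey)
  } else {
    y[1L] <- long_run_slope * x[1L]
    for (t in 2:N)
      y[t] <- y[t - 1L] + adjustment * (y[t - 1L] - long_run_slope * x[t - 1L]) +
        ey[t]
  }
  keep <- (burn_in + 1L):N
  ts_table(cbind(Y = y[keep], X = x[keep]), frequency = 1)
}
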