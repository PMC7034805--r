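#' Fit a Koyck (geometric) distributed lag model by instrumental variables
#'
#' The geometric DLM `Y_t = alpha + beta (X_t + phi X_{t-1} + ...) + eps_t`
#' is estimated in its transformed finite form
#' `Y_t = delta1 + delta2 Y_{t-1} + delta3 X_t + nu_t`.
#' Because `Y_{t-1}` and `nu_t` are correlated by construction, the deltas
#' are estimated by two-stage least squares with the just-identified
#' instrument set `(1, X_t, X_{t-1})` — `X_{t-1}` instruments `Y_{t-1}`.
#' The geometric-form parameters are recovered as
#' `alpha = delta1 / (1 - delta2)`, `beta = delta3`, `phi = delta2`.
#'
#' Endogeneity diagnostics are attached: a weak-instruments F test of the
#' excluded instrument in the first stage, and the Wu-Hausman test in its
#' auxiliary-regression form (structural OLS augmented with the first-stage
#' residual). Both are asymptotic; a warning is raised below 50 effective
#' observations.
#'
#' @param x single predictor series.
#' @param y response series of the same length.
#' @return A `"dlag"` fit of family `"koyck"` with elements `geometric`
#'   (alpha, beta, phi, deltas), `diagnostics` (weak instruments,
#'   Wu-Hausman), `wald` (joint significance of the non-intercept
#'   coefficients using the 2SLS covariance), and `first_stage`.
#' @examples
#' d <- simulate_ardl(sim_spec(n = 200, k = 1, p = 0, q = 1,
#'                             gamma = 0.5, seed = 3))
#' fit <- koyck_dlm(x = d$values[, "X1"], y = d$values[, "Y"])
#' fit$geometric
#' @export
koyck_dlm <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(y)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant; Koyck model unidentified", call. = FALSE)
  n_eff <- n - 1L
  if (n_eff < 50L)
    warning("Koyck IV diagnostics are asymptotic; use cautiously with n_eff < 50",
            call. = FALSE)
  yy <- y[2:n]
  Z <- cbind(`(Intercept)` = 1, `Y.1` = y[1:(n - 1L)], `X.t` = x[2:n])
  W <- cbind(1, x[2:n], x[1:(n - 1L)])   # instruments: 1, X_t, X_{t-1}
  colnames(W) <- c("(Intercept)", "X.t", "X.1")
  fit <- fit_tsls(Z, W, yy, endogenous = "Y.1", excluded = "X.1")
  fit$family <- "koyck"
  fit$call <- match.call()
  d <- fit$coefficients
  fit$geometric <- koyck_geometric(d[["(Intercept)"]], d[["Y.1"]], d[["X.t"]])
  fit$design <- list(response = "Y", predictor_lags = list(X = 0L),
                     response_lags = 1L, intercept = TRUE, trend = FALSE,
                     max_lag = 1L, q = 1L)
  fit$history <- list(x = list(X = x), y = y, max_lag = 1L)
  fit$frequency <- 1
  fit
}

#' Recover the geometric-form coefficients of a Koyck model
#'
#' @param delta1,delta2,delta3 coefficients of the transformed regression
#'   `Y_t = delta1 + delta2 Y_{t-1} + delta3 X_t + nu_t`.
#' @return list with `alpha = delta1 / (1 - delta2)`, `beta = delta3`,
#'   `phi = delta2`, and the source `deltas`.
#' @examples
#' koyck_geometric(0.008036, 0.733753, -2.553163)$alpha
#' @export
koyck_geometric <- function(delta1, delta2, delta3) {
  list(alpha = delta1 / (1 - delta2), beta = delta3, phi = delta2,
       deltas = c(delta1 = delta1, delta2 = delta2, delta3 = delta3))
}

# Two-stage least squares with diagnostics. Z: structural regressors,
# W: instruments (must span the exogenous columns of Z), y: response.
fit_tsls <- function(Z, W, y, endogenous, excluded) {
  qw <- qr(W)
  if (qw$rank < ncol(W))
    stop("singular instrument matrix", call. = FALSE)
  n_eff <- length(y)
  p <- ncol(Z)
  Zhat <- qr.fitted(qw, Z)                # project regressors on instruments
  qz <- qr(Zhat)
  if (qz$rank < p) stop("singular design after projection", call. = FALSE)
  b <- qr.coef(qz, y)
  names(b) <- colnames(Z)
  res <- drop(y - Z %*% b)                # structural residuals
  fitted <- drop(Z %*% b)
  df_resid <- n_eff - p
  sigma2 <- sum(res^2) / df_resid
  vc <- sigma2 * chol2inv(qr.R(qz))
  dimnames(vc) <- list(colnames(Z), colnames(Z))
  se <- sqrt(diag(vc))
  tval <- b / se
  pval <- 2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE)
  sst <- sum((y - mean(y))^2)
  ssr <- sum(res^2)
  r2 <- 1 - ssr / sst
  adj <- 1 - (1 - r2) * (n_eff - 1) / df_resid
  # Wald test: all non-intercept coefficients zero, 2SLS covariance
  idx <- which(colnames(Z) != "(Intercept)")
  bw <- b[idx]
  Vw <- vc[idx, idx, drop = FALSE]
  wald_chi <- drop(t(bw) %*% solve(Vw, bw))
  wald <- c(value = wald_chi / length(idx), df1 = length(idx), df2 = df_resid,
            pvalue = stats::pf(wald_chi / length(idx), length(idx), df_resid,
                               lower.tail = FALSE))
  ll <- -n_eff / 2 * (log(2 * pi) + log(ssr / n_eff) + 1)
  npar <- p + 1
  # first stage: endogenous column on all instruments
  fs <- fit_ols(W, Z[, endogenous], family = "ols",
                has_intercept = "(Intercept)" %in% colnames(W))
  tx <- fs$coef_table[excluded, "t value"]
  weak <- c(statistic = unname(tx^2), df1 = 1, df2 = fs$df_resid,
            p.value = stats::pf(tx^2, 1, fs$df_resid, lower.tail = FALSE))
  # Wu-Hausman: augment structural OLS with first-stage residual, F-test it
  aug <- cbind(Z, .fsres = fs$residuals)
  augfit <- fit_ols(aug, y, family = "ols")
  twh <- augfit$coef_table[".fsres", "t value"]
  wh <- c(statistic = unname(twh^2), df1 = 1, df2 = augfit$df_resid,
          p.value = stats::pf(twh^2, 1, augfit$df_resid, lower.tail = FALSE))
  diag_tab <- rbind(`Weak instruments` = weak, `Wu-Hausman` = wh)
  obj <- list(
    family = "tsls", coefficients = b,
    coef_table = cbind(Estimate = b, `Std. Error` = se,
                       `t value` = tval, `Pr(>|t|)` = pval),
    vcov = vc, residuals = res, fitted.values = fitted, y = y, X = Z,
    instruments = W, n_eff = n_eff, df_resid = df_resid,
    sigma = sqrt(sigma2), r.squared = r2, adj.r.squared = adj,
    fstatistic = c(value = NA_real_, df1 = NA_real_, df2 = NA_real_),
    wald = wald, logLik = ll, npar = npar,
    aic = -2 * ll + 2 * npar, bic = -2 * ll + log(n_eff) * npar,
    has_intercept = TRUE, first_stage = fs,
    diagnostics = as.data.frame(diag_tab))
  class(obj) <- "dlag"
  obj
}
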