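#' Fit a finite distributed lag model
#'
#' Regresses the response on lags `0..q` of every predictor in the formula,
#' optionally removing chosen lags per predictor. The effective sample is the
#' contiguous tail of the data: the first `q` rows are dropped, so
#' `n_eff = n - q` whatever lags are removed.
#'
#' @param formula model formula `Y ~ X1 + X2`; append `-1` to drop the
#'   intercept. Lags are generated automatically, never written in the
#'   formula.
#' @param data a [ts_table()], data frame or numeric matrix holding all
#'   series named in the formula.
#' @param q finite lag length (non-negative integer).
#' @param remove named list of lags to drop per predictor, e.g.
#'   `list(X = c(2, 3), Z = c(0))`; including 0 removes the contemporaneous
#'   term of that predictor.
#' @param frequency observations per cycle, used when `data` is not already a
#'   `ts_table` (stored for diagnostics defaults).
#' @return A `"dlag"` fit of family `"finite"`.
#' @examples
#' d <- simulate_ardl(sim_spec(n = 120, k = 1, p = 2, q = 0, seed = 1))
#' fit <- finite_dlm(Y ~ X1, data = d, q = 3)
#' coef(fit)
#' @seealso [poly_dlm()], [ardl_dlm()], [forecast.dlag()]
#' @export
finite_dlm <- function(formula, data, q, remove = NULL, frequency = 1) {
  tab <- as_ts_table(data, frequency)
  pf <- parse_dlag_formula(formula, tab)
  q <- check_count(q, "q")
  if (q >= tab$n) stop("q must be smaller than the series length", call. = FALSE)
  lagsets <- lapply(pf$predictors, function(nm) {
    keep <- 0:q
    rem <- remove[[nm]]
    if (!is.null(rem)) {
      rem <- as.integer(rem)
      if (any(!rem %in% 0:q))
        stop("removed lags for '", nm, "' must lie in 0..q", call. = FALSE)
      keep <- setdiff(keep, rem)
    }
    keep
  })
  names(lagsets) <- pf$predictors
  if (all(lengths(lagsets) == 0L))
    stop("empty design: every lag of every predictor was removed", call. = FALSE)
  y <- ts_get(tab, pf$response)
  X <- assemble_design(tab, lagsets, response_lags = integer(0),
                       response = pf$response, max_lag = q,
                       intercept = pf$intercept, trend = FALSE)
  fit <- fit_ols(X, y[(q + 1L):tab$n], family = "finite")
  fit$call <- match.call()
  fit$design <- list(response = pf$response, predictor_lags = lagsets,
                     response_lags = integer(0), intercept = pf$intercept,
                     trend = FALSE, max_lag = q, q = q)
  fit$history <- history_tail(tab, pf, q)
  fit$frequency <- tab$frequency
  fit
}

#' Fit an Almon polynomial distributed lag model
#'
#' Restricts the lag weights of a single-predictor finite DLM of order `q` to
#' a polynomial of order `k` in the lag index: transformed regressors
#' `z_j[t] = sum_s s^j x[t - s]` are built for `j = 0..k` and the response is
#' regressed on an intercept plus `z_0..z_k`. The original lag weights
#' `beta_0..beta_q` are recovered through the linear map `beta = S gamma`
#' with `S[s, j] = s^j`, and their standard errors through
#' `S cov(gamma) S'`.
#'
#' @param x single predictor series.
#' @param y response series.
#' @param q finite lag length.
#' @param k polynomial order, `0 <= k <= q`.
#' @param show_beta recover the lag weights and their tests (default TRUE).
#' @return A `"dlag"` fit of family `"poly"`; the `poly_weights` element
#'   holds `gamma`, the transform matrix `S`, and the `beta` table.
#' @examples
#' d <- simulate_ardl(sim_spec(n = 150, k = 1, p = 3, q = 0, seed = 2))
#' fit <- poly_dlm(x = d$values[, "X1"], y = d$values[, "Y"], q = 3, k = 2)
#' fit$poly_weights$beta_table
#' @export
poly_dlm <- function(x, y, q, k, show_beta = TRUE) {
  q <- check_count(q, "q"); k <- check_count(k, "k")
  if (k > q) stop("polynomial order k must not exceed the lag length q", call. = FALSE)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(y)
  if (q >= n) stop("q must be smaller than the series length", call. = FALSE)
  lx <- build_lag_matrix(x, 0:q, "x")          # (n - q) x (q + 1)
  S <- outer(0:q, 0:k, function(s, j) ifelse(j == 0, 1, s^j))
  dimnames(S) <- list(paste0("beta.", 0:q), paste0("z.", 0:k))
  Z <- lx %*% S
  if (q * k > 60)
    warning("high q*k: raw-power Almon basis may be ill-conditioned", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, Z)
  fit <- fit_ols(X, y[(q + 1L):n], family = "poly")
  fit$call <- match.call()
  fit$design <- list(response = "y", predictor_lags = list(x = 0:q),
                     response_lags = integer(0), intercept = TRUE,
                     trend = FALSE, max_lag = q, q = q, k = k)
  if (show_beta) {
    gamma <- fit$coefficients[-1L]
    Vg <- fit$vcov[-1L, -1L, drop = FALSE]
    beta <- drop(S %*% gamma)
    Vb <- S %*% Vg %*% t(S)
    se <- sqrt(pmax(diag(Vb), 0))
    tval <- beta / se
    pval <- 2 * stats::pt(abs(tval), fit$df_resid, lower.tail = FALSE)
    fit$poly_weights <- list(
      k = k, gamma = gamma, gamma_vcov = Vg, transform = S,
      beta = beta, beta_vcov = Vb,
      beta_table = cbind(Estimate = beta, `Std. Error` = se,
                         `t value` = tval, `Pr(>|t|)` = pval))
  }
  fit$history <- list(x = list(x = x), y = y, max_lag = q)
  fit$frequency <- 1
  fit
}

# ---- shared formula / design helpers ---------------------------------------

parse_dlag_formula <- function(formula, tab) {
  if (is.character(formula)) formula <- stats::as.formula(formula)
  tf <- stats::terms(formula)
  if (attr(tf, "response") != 1L)
    stop("formula must have a response, e.g. Y ~ X1 + X2", call. = FALSE)
  vars <- as.character(attr(tf, "variables"))[-1L]
  response <- vars[1L]
  predictors <- attr(tf, "term.labels")
  if (length(predictors) == 0L)
    stop("formula needs at least one predictor series", call. = FALSE)
  if (!all(predictors %in% tab$names) || !response %in% tab$names) {
    missing <- setdiff(c(response, predictors), tab$names)
    stop("series not found in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  list(response = response, predictors = predictors,
       intercept = attr(tf, "intercept") == 1L)
}

# Assemble the regression design on the common effective sample
# (rows max_lag+1 .. n of the original index).
assemble_design <- function(tab, predictor_lags, response_lags, response,
                            max_lag, intercept, trend) {
  n <- tab$n
  rows <- (max_lag + 1L):n
  cols <- list()
  if (intercept) cols[["(Intercept)"]] <- rep(1, length(rows))
  if (trend) cols[["trend"]] <- as.numeric(rows)
  for (nm in names(predictor_lags)) {
    v <- ts_get(tab, nm)
    for (s in predictor_lags[[nm]])
      cols[[lag_labels(nm, s)]] <- v[rows - s]
  }
  for (lag in response_lags) {
    yv <- ts_get(tab, response)
    cols[[paste0(response, ".", lag)]] <- yv[rows - lag]
  }
  if (length(cols) == 0L) stop("empty design", call. = FALSE)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

history_tail <- function(tab, pf, max_lag) {
  xs <- lapply(pf$predictors, function(nm) ts_get(tab, nm))
  names(xs) <- pf$predictors
  list(x = xs, y = ts_get(tab, pf$response), max_lag = max_lag)
}

check_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x != floor(x))
    stop("'", what, "' must be a single non-negative integer", call. = FALSE)
  as.integer(x)
}
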