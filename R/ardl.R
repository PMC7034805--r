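#' Fit an autoregressive distributed lag (ARDL) model
#'
#' Regresses `Y_t` on an intercept, lags `0..p_i` of each predictor, and
#' lags `1..q` of the response, with optional per-series lag removal. The
#' effective sample drops the first `max(p_max, q)` rows of the data, so all
#' declared orders count towards the alignment even when their lags are
#' removed.
#'
#' @param formula model formula `Y ~ X1 + X2` (append `-1` to drop the
#'   intercept).
#' @param data a [ts_table()], data frame or matrix with all named series.
#' @param p short-run lag order: a single integer applied to every predictor
#'   or a named vector of per-predictor orders.
#' @param q autoregressive order (lags of the response).
#' @param remove list with elements `p` (named list of predictor lags to
#'   drop, 0 allowed) and `q` (vector of response lags to drop), e.g.
#'   `list(p = list(X = c(0, 2)), q = c(1))`.
#' @param frequency observations per cycle (metadata).
#' @return A `"dlag"` fit of family `"ardl"`.
#' @examples
#' d <- simulate_ardl(sim_spec(n = 200, k = 2, p = 1, q = 1, seed = 4))
#' fit <- ardl_dlm(Y ~ X1 + X2, data = d, p = 1, q = 1)
#' summary(fit)
#' @export
ardl_dlm <- function(formula, data, p = 1, q = 1, remove = NULL, frequency = 1) {
  tab <- as_ts_table(data, frequency)
  pf <- parse_dlag_formula(formula, tab)
  q <- check_count(q, "q")
  p_orders <- resolve_p_orders(p, pf$predictors)
  rem_p <- remove$p
  rem_q <- as.integer(remove$q %||% integer(0))
  if (any(!rem_q %in% seq_len(q)))
    stop("removed response lags must lie in 1..q", call. = FALSE)
  lagsets <- lapply(pf$predictors, function(nm) {
    keep <- 0:p_orders[[nm]]
    rem <- rem_p[[nm]]
    if (!is.null(rem)) {
      rem <- as.integer(rem)
      if (any(!rem %in% keep))
        stop("removed lags for '", nm, "' must lie in 0..p", call. = FALSE)
      keep <- setdiff(keep, rem)
    }
    keep
  })
  names(lagsets) <- pf$predictors
  response_lags <- setdiff(seq_len(q), rem_q)
  if (all(lengths(lagsets) == 0L) && length(response_lags) == 0L && !pf$intercept)
    stop("empty design: all predictor and response lags removed", call. = FALSE)
  max_lag <- max(c(unlist(p_orders), q))
  if (max_lag >= tab$n)
    stop("max(p, q) must be smaller than the series length", call. = FALSE)
  y <- ts_get(tab, pf$response)
  X <- assemble_design(tab, lagsets, response_lags, pf$response,
                       max_lag, pf$intercept, trend = FALSE)
  fit <- fit_ols(X, y[(max_lag + 1L):tab$n], family = "ardl")
  fit$call <- match.call()
  fit$design <- list(response = pf$response, predictor_lags = lagsets,
                     response_lags = response_lags, intercept = pf$intercept,
                     trend = FALSE, max_lag = max_lag, p = p_orders, q = q)
  fit$history <- history_tail(tab, pf, max_lag)
  fit$frequency <- tab$frequency
  fit
}

resolve_p_orders <- function(p, predictors) {
  if (is.data.frame(p)) p <- unlist(p)
  if (length(p) == 1L && is.null(names(p))) {
    out <- stats::setNames(rep(check_count(p, "p"), length(predictors)), predictors)
  } else {
    p <- unlist(p)
    if (!all(predictors %in% names(p)))
      stop("per-predictor 'p' must name every predictor", call. = FALSE)
    out <- stats::setNames(vapply(predictors, function(nm)
      check_count(p[[nm]], paste0("p[", nm, "]")), integer(1)), predictors)
  }
  as.list(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
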