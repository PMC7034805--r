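#' Forecast from a fitted distributed-lag model
#'
#' @param object a fitted model.
#' @param ... passed to methods.
#' @export
forecast <- function(object, ...) UseMethod("forecast")

#' Recursive multi-step forecasts with Monte Carlo prediction intervals
#'
#' Point forecasts are computed by iterating the fitted equation forward,
#' substituting predicted response values for response lags that fall beyond
#' the observed sample. When `interval = TRUE`, `nSim` trajectories are
#' simulated: at every step an iid Gaussian shock is added, with standard
#' deviation equal to the empirical standard deviation of the observed
#' response series (the alternative `shock = "residual"` uses the residual
#' standard error instead), and the simulated values — including their
#' shocks — feed back through the lagged-response terms, so intervals widen
#' with the horizon for autoregressive models. Interval bounds are the
#' `(1 - level)/2` and `1 - (1 - level)/2` empirical percentiles per step
#' (linear interpolation between order statistics).
#'
#' @param object a `"dlag"` fit (finite, poly, koyck or ardl family).
#' @param x_new matrix of future predictor values, one row per predictor in
#'   the fitting order and `h` columns (ignored for models without
#'   predictors).
#' @param h forecast horizon.
#' @param interval compute Monte Carlo prediction intervals.
#' @param level interval level (default 0.95).
#' @param nSim number of simulated trajectories.
#' @param seed RNG seed used for the simulation (recorded in the result).
#' @param shock `"empirical"` (variance of the observed response, the
#'   default) or `"residual"` (residual variance).
#' @param ... unused.
#' @return A `"dlag_forecast"` list: `mean` (point forecasts), `lower`,
#'   `upper`, `level`, `h`, `nSim`, `seed`.
#' @examples
#' d <- simulate_ardl(sim_spec(n = 150, k = 1, p = 1, q = 1, seed = 5))
#' fit <- ardl_dlm(Y ~ X1, data = d, p = 1, q = 1)
#' forecast(fit, x_new = matrix(c(0.1, 0.2), 1, 2), h = 2,
#'          interval = TRUE, nSim = 200, seed = 1)
#' @export
forecast.dlag <- function(object, x_new = NULL, h = 1, interval = FALSE,
                          level = 0.95, nSim = 500, seed = NULL,
                          shock = c("empirical", "residual"), ...) {
  shock <- match.arg(shock)
  h <- check_count(h, "h")
  if (h < 1L) stop("h must be at least 1", call. = FALSE)
  des <- object$design
  hist <- object$history
  k <- length(hist$x)
  if (k > 0L) {
    if (is.null(x_new)) stop("x_new is required: supply a ", k, " x ", h,
                             " matrix of future predictor values", call. = FALSE)
    x_new <- rbind(x_new)
    if (nrow(x_new) != k || ncol(x_new) != h)
      stop("x_new has the wrong shape: expected ", k, " x ", h,
           " (one row per predictor)", call. = FALSE)
    rownames(x_new) <- names(hist$x)
  }
  point <- recurse_forecast(object, x_new, h, shocks = NULL)
  lower <- upper <- NULL
  if (interval) {
    if (!is.null(seed)) set.seed(seed)
    sd_shock <- if (shock == "empirical") stats::sd(hist$y) else object$sigma
    paths <- matrix(NA_real_, nSim, h)
    for (s in seq_len(nSim))
      paths[s, ] <- recurse_forecast(object, x_new, h,
                                     shocks = stats::rnorm(h, 0, sd_shock))
    qs <- apply(paths, 2, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2))
    lower <- qs[1L, ]; upper <- qs[2L, ]
  }
  structure(list(mean = point, lower = lower, upper = upper, level = level,
                 h = h, nSim = if (interval) nSim else NA_integer_,
                 seed = seed),
            class = "dlag_forecast")
}

#' @export
print.dlag_forecast <- function(x, digits = 6, ...) {
  tab <- data.frame(step = seq_len(x$h), forecast = x$mean)
  if (!is.null(x$lower)) {
    tab$lower <- x$lower; tab$upper <- x$upper
    names(tab)[3:4] <- paste0(c("lower", "upper"), format(100 * x$level), "%")
  }
  print(tab, digits = digits, row.names = FALSE)
  invisible(x)
}

# one forward pass of the fitted recursion; shocks NULL -> deterministic path
recurse_forecast <- function(object, x_new, h, shocks = NULL) {
  des <- object$design
  hist <- object$history
  b <- object$coefficients
  n <- length(hist$y)
  yext <- c(hist$y, rep(NA_real_, h))
  xext <- lapply(names(hist$x), function(nm)
    c(hist$x[[nm]], if (!is.null(x_new)) x_new[nm, ] else numeric(0)))
  names(xext) <- names(hist$x)
  # poly family: forecast through the recovered lag weights
  poly <- object$family == "poly"
  out <- numeric(h)
  for (j in seq_len(h)) {
    t <- n + j
    val <- 0
    if (des$intercept) val <- val + b[["(Intercept)"]]
    if (isTRUE(des$trend)) val <- val + b[["trend"]] * t
    for (lag in des$response_lags)
      val <- val + b[[paste0(des$response, ".", lag)]] * yext[t - lag]
    if (poly) {
      bw <- object$poly_weights$beta
      xv <- xext[[1L]]
      for (s in 0:des$q) val <- val + bw[s + 1L] * xv[t - s]
    } else {
      for (nm in names(des$predictor_lags)) {
        lags <- des$predictor_lags[[nm]]
        labs <- lag_labels(nm, lags)
        for (i in seq_along(lags))
          val <- val + b[[labs[i]]] * xext[[nm]][t - lags[i]]
      }
    }
    if (!is.null(shocks)) val <- val + shocks[j]
    yext[t] <- val
    out[j] <- val
  }
  out
}
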