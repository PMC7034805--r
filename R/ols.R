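#' Least-squares engine shared by all model families
#'
#' Ordinary least squares of `y` on the columns of `X` (an intercept, when
#' wanted, is an explicit `"(Intercept)"` column of `X`). Returns a fitted
#' `"dlag"` object carrying the coefficient table, covariance, residuals,
#' fitted values and information criteria. The Gaussian log-likelihood counts
#' the error variance as one extra parameter, so `AIC()`/`BIC()` agree with
#' mainstream linear-model summaries.
#'
#' @param X numeric design matrix with column labels.
#' @param y numeric response aligned to the rows of `X`.
#' @param family tag recorded on the fit (`"finite"`, `"poly"`, `"koyck"`,
#'   `"ardl"`, `"cecm"`, `"ecm"`, or `"ols"`).
#' @param has_intercept whether `X` contains an `"(Intercept)"` column; used
#'   for the R-squared and model-F conventions (centred total sum of squares
#'   with an intercept, uncentred without).
#' @return object of class `"dlag"`; see [summary.dlag()].
#' @keywords internal
fit_ols <- function(X, y, family = "ols", has_intercept = "(Intercept)" %in% colnames(X)) {
  X <- as.matrix(X)
  n_eff <- length(y)
  p <- ncol(X)
  if (n_eff < p)
    stop("fewer observations (", n_eff, ") than coefficients (", p, ")", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # lm fit kept alongside for the diagnostic tests that expect an lm object
  lm_fit <- stats::lm(y ~ 0 + X)
  coefs <- stats::coef(lm_fit)
  names(coefs) <- colnames(X)
  res <- stats::residuals(lm_fit)
  fit <- stats::fitted(lm_fit)
  ssr <- sum(res^2)
  df_resid <- n_eff - p
  sigma2 <- ssr / df_resid
  XtXinv <- chol2inv(qr.R(qx))
  vc <- sigma2 * XtXinv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE)
  sst <- if (has_intercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- 1 - ssr / sst
  adj <- 1 - (1 - r2) * (n_eff - has_intercept) / df_resid
  nslope <- p - has_intercept
  fstat <- if (nslope > 0 && df_resid > 0)
    c(value = (sst - ssr) / nslope / sigma2, df1 = nslope, df2 = df_resid)
  else c(value = NA_real_, df1 = NA_real_, df2 = NA_real_)
  ll <- -n_eff / 2 * (log(2 * pi) + log(ssr / n_eff) + 1)
  npar <- p + 1  # + error variance
  obj <- list(
    family = family,
    coefficients = coefs,
    coef_table = cbind(Estimate = coefs, `Std. Error` = se,
                       `t value` = tval, `Pr(>|t|)` = pval),
    vcov = vc, residuals = res, fitted.values = fit, y = y, X = X,
    n_eff = n_eff, df_resid = df_resid, sigma = sqrt(sigma2),
    r.squared = r2, adj.r.squared = adj, fstatistic = fstat,
    logLik = ll, npar = npar,
    aic = -2 * ll + 2 * npar, bic = -2 * ll + log(n_eff) * npar,
    has_intercept = has_intercept, lm_fit = lm_fit)
  class(obj) <- "dlag"
  obj
}

#' @export
coef.dlag <- function(object, ...) object$coefficients

#' @export
vcov.dlag <- function(object, ...) object$vcov

#' @export
residuals.dlag <- function(object, ...) object$residuals

#' @export
fitted.dlag <- function(object, ...) object$fitted.values

#' @export
nobs.dlag <- function(object, ...) object$n_eff

#' @export
logLik.dlag <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n_eff,
            class = "logLik")
}

#' @export
print.dlag <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Distributed lag model (", x$family, "), n_eff = ", x$n_eff, "\n\n", sep = "")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Summarise a fitted distributed-lag model
#'
#' @param object a `"dlag"` fit.
#' @param ... unused.
#' @return An object of class `"summary.dlag"` printing the coefficient
#'   table, residual standard error, R-squared values, the model F (or Wald)
#'   test, information criteria, and family-specific blocks (geometric
#'   coefficients and endogeneity diagnostics for Koyck fits, recovered lag
#'   weights for polynomial fits).
#' @export
summary.dlag <- function(object, ...) {
  out <- list(family = object$family, call = object$call,
              residuals = stats::quantile(object$residuals,
                                          c(0, 0.25, 0.5, 0.75, 1)),
              coef_table = object$coef_table,
              sigma = object$sigma, df_resid = object$df_resid,
              r.squared = object$r.squared, adj.r.squared = object$adj.r.squared,
              fstatistic = object$fstatistic, wald = object$wald,
              aic = object$aic, bic = object$bic,
              diagnostics = object$diagnostics,
              geometric = object$geometric, poly_weights = object$poly_weights)
  class(out) <- "summary.dlag"
  out
}

#' @export
print.summary.dlag <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  if (!is.null(x$call)) { cat("Call:\n"); print(x$call); cat("\n") }
  cat("Residuals:\n")
  rq <- x$residuals; names(rq) <- c("Min", "1Q", "Median", "3Q", "Max")
  print(round(rq, digits))
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coef_table, digits = digits, signif.stars = TRUE)
  cat("\nResidual standard error:", format(x$sigma, digits = digits),
      "on", x$df_resid, "degrees of freedom\n")
  cat("Multiple R-squared:", format(x$r.squared, digits = digits),
      " Adjusted R-squared:", format(x$adj.r.squared, digits = digits), "\n")
  if (!is.null(x$wald)) {
    cat("Wald test:", format(x$wald["value"], digits = digits), "on",
        x$wald["df1"], "and", x$wald["df2"], "DF, p-value:",
        format.pval(x$wald["pvalue"], digits = digits), "\n")
  } else if (is.finite(x$fstatistic["value"])) {
    pv <- stats::pf(x$fstatistic["value"], x$fstatistic["df1"],
                    x$fstatistic["df2"], lower.tail = FALSE)
    cat("F-statistic:", format(x$fstatistic["value"], digits = digits), "on",
        x$fstatistic["df1"], "and", x$fstatistic["df2"],
        "DF, p-value:", format.pval(pv, digits = digits), "\n")
  }
  cat("AIC:", format(x$aic, digits = digits),
      " BIC:", format(x$bic, digits = digits), "\n")
  if (!is.null(x$diagnostics)) {
    cat("\nDiagnostic tests:\n")
    print(x$diagnostics, digits = digits)
  }
  if (!is.null(x$geometric)) {
    cat("\nGeometric coefficients:\n")
    print(round(unlist(x$geometric[c("alpha", "beta", "phi")]), 8))
  }
  if (!is.null(x$poly_weights)) {
    cat("\nRecovered lag weights (beta):\n")
    stats::printCoefmat(x$poly_weights$beta_table, digits = digits)
  }
  invisible(x)
}

#' @export
plot.dlag <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  graphics::plot(x$y, type = "l", ylab = "response",
                 main = paste0("Observed and fitted (", x$family, ")"), ...)
  graphics::lines(x$fitted.values, col = 2)
  graphics::plot(x$residuals, type = "h", ylab = "residual", main = "Residuals")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

# F test of H0: R b = 0 via restricted/unrestricted SSR comparison
ssr_f_test <- function(y, X_unrestricted, X_restricted, r) {
  ssr_u <- sum(qr.resid(qr(X_unrestricted), y)^2)
  ssr_r <- if (is.null(X_restricted) || ncol(X_restricted) == 0L) sum(y^2)
           else sum(qr.resid(qr(X_restricted), y)^2)
  df_u <- length(y) - ncol(X_unrestricted)
  Fv <- ((ssr_r - ssr_u) / r) / (ssr_u / df_u)
  c(value = Fv, df1 = r, df2 = df_u,
    pvalue = stats::pf(Fv, r, df_u, lower.tail = FALSE))
}
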