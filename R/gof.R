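#' Goodness-of-fit accuracy battery
#'
#' Computes, for each fitted model, MAE, MPE, MAPE, sMAPE, MASE, MSE, MRAE,
#' GMRAE and — when two or more models are supplied — MBRAE and UMBRAE, over
#' the aligned (actual, fitted) pairs of each model's effective sample.
#'
#' Conventions: with `e_t = y_t - yhat_t` and in-sample one-step naive
#' benchmark error `e*_t = y_t - y_{t-1}`,
#' `MASE = mean|e| / mean|e*|` (both means over the benchmark-aligned
#' subsample, so the naive forecast itself scores exactly 1),
#' `MRAE = mean|e/e*|`,
#' `GMRAE = exp(mean log|e/e*|)`, `BRAE_t = |e_t|/(|e_t| + |e*_t|)`,
#' `MBRAE = mean BRAE` and `UMBRAE = MBRAE/(1 - MBRAE)`. Percentage-type
#' measures (MPE, MAPE, sMAPE) are reported on the fraction scale. Terms
#' with `y_t = 0` (for MPE/MAPE) or `e*_t = 0` (for relative measures) are
#' dropped, with the dropped count recorded in an attribute.
#'
#' @param ... one or more `"dlag"` fits (named arguments name the rows).
#' @return data frame of class `"gof_table"`, one row per model, columns
#'   `n, MAE, MPE, MAPE, sMAPE, MASE, MSE, MRAE, GMRAE[, MBRAE, UMBRAE]`.
#' @examples
#' d <- simulate_ardl(sim_spec(n = 150, k = 1, p = 1, q = 1, seed = 6))
#' f1 <- ardl_dlm(Y ~ X1, data = d, p = 1, q = 1)
#' f2 <- finite_dlm(Y ~ X1, data = d, q = 2)
#' gof(ardl = f1, dlm = f2)
#' @export
gof <- function(...) {
  models <- list(...)
  if (length(models) == 1L && is.list(models[[1L]]) && !inherits(models[[1L]], "dlag"))
    models <- models[[1L]]
  nm <- names(models)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- paste0("model", seq_along(models))
  rows <- lapply(models, function(m) accuracy_row(m$y, m$fitted.values))
  out <- do.call(rbind, rows)
  rownames(out) <- nm
  if (length(models) < 2L) out$MBRAE <- out$UMBRAE <- NULL
  class(out) <- c("gof_table", "data.frame")
  out
}

accuracy_row <- function(actual, fitted) {
  if (length(actual) < 2L) stop("need at least 2 observations", call. = FALSE)
  e <- actual - fitted
  bench <- actual[-1L] - actual[-length(actual)]   # naive one-step errors
  eb <- e[-1L]                                     # model errors aligned to bench
  dropped <- 0L
  ok_y <- actual != 0
  dropped <- dropped + sum(!ok_y)
  ok_b <- bench != 0
  dropped <- dropped + sum(!ok_b)
  rel <- abs(eb[ok_b] / bench[ok_b])
  brae <- abs(eb) / (abs(eb) + abs(bench))
  brae <- brae[is.finite(brae)]                    # both-zero terms drop out
  mbrae <- mean(brae)
  naive_mae <- mean(abs(bench))
  out <- data.frame(
    n = length(actual),
    MAE = mean(abs(e)),
    MPE = mean(e[ok_y] / actual[ok_y]),
    MAPE = mean(abs(e[ok_y] / actual[ok_y])),
    sMAPE = mean(2 * abs(e) / (abs(actual) + abs(fitted))),
    MASE = mean(abs(eb)) / naive_mae,
    MSE = mean(e^2),
    MRAE = mean(rel),
    GMRAE = if (all(rel > 0)) exp(mean(log(rel))) else 0,
    MBRAE = mbrae,
    UMBRAE = mbrae / (1 - mbrae))
  attr(out, "dropped") <- dropped
  if (length(rel) == 0L) attr(out, "undefined") <- TRUE
  out
}

#' @export
print.gof_table <- function(x, digits = 7, ...) {
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}

#' Sort models by an accuracy or information criterion
#'
#' @param x a [gof()] table, or any data frame with a column named after
#'   `score`, or a `"dlag"` model list.
#' @param score one of `"AIC"`, `"BIC"`, `"MASE"`, `"MAPE"`, `"sMAPE"`,
#'   `"MRAE"`, `"GMRAE"`, `"MBRAE"`.
#' @return the rows of `x` in ascending `score` order (ties broken by row
#'   name for determinism), with the score column first.
#' @export
sort_score <- function(x, score = "MASE") {
  valid <- c("AIC", "BIC", "MASE", "MAPE", "sMAPE", "MRAE", "GMRAE", "MBRAE")
  score <- toupper(score)
  if (score == "SMAPE") score <- "sMAPE"
  if (!score %in% valid)
    stop("unknown score '", score, "'; valid scores: ",
         paste(valid, collapse = ", "), call. = FALSE)
  if (!score %in% names(x))
    stop("column '", score, "' not present in the table", call. = FALSE)
  ord <- order(x[[score]], rownames(x))
  x[ord, c("n", score)[c("n", score) %in% names(x)], drop = FALSE]
}

#' Search the lag length of finite and polynomial DLMs
#'
#' Fits every candidate order in `q_min..q_max` (and, for polynomial models
#' with `k_order` unset, every polynomial order `k <= q`), computes the full
#' accuracy battery, AIC/BIC, adjusted R-squared and the Ljung-Box residual
#' p-value, and ranks the candidates by the chosen criterion (descending for
#' `radj`, ascending otherwise). All candidates are fitted on the common
#' effective sample implied by `q_max` (the first `q_max` rows are dropped
#' for every candidate) so that likelihood-based criteria are comparable
#' across orders.
#'
#' @param formula,data as for [finite_dlm()] (`dlm` type).
#' @param x,y single series, used when `model_type = "poly"`.
#' @param q_min,q_max search range for the lag length.
#' @param k_order fixed polynomial order (`poly` type); `NULL` searches all
#'   `k <= q`.
#' @param model_type `"dlm"` or `"poly"`.
#' @param criterion one of `"MASE"`, `"AIC"`, `"BIC"`, `"GMRAE"`, `"MBRAE"`,
#'   `"radj"`.
#' @param frequency observations per cycle (metadata).
#' @return data frame ranked by the criterion, one row per candidate with
#'   columns `q[, k]`, the measures, and `LjungBox.p`.
#' @export
search_finite_order <- function(formula = NULL, data = NULL, x = NULL, y = NULL,
                                q_min = 1, q_max = 10, k_order = NULL,
                                model_type = c("dlm", "poly"),
                                criterion = c("MASE", "AIC", "BIC", "GMRAE",
                                              "MBRAE", "radj"),
                                frequency = 1) {
  model_type <- match.arg(model_type)
  criterion <- match.arg(criterion)
  q_min <- check_count(q_min, "q_min"); q_max <- check_count(q_max, "q_max")
  if (q_min > q_max) stop("q_min must not exceed q_max", call. = FALSE)
  if (model_type == "poly") {
    if (is.null(x) || is.null(y))
      stop("poly search needs the single series x and y", call. = FALSE)
    grid <- do.call(rbind, lapply(q_min:q_max, function(q) {
      ks <- if (is.null(k_order)) 0:q else k_order[k_order <= q]
      if (length(ks) == 0L) return(NULL)
      data.frame(q = q, k = ks)
    }))
    n <- length(y)
    fits <- lapply(seq_len(nrow(grid)), function(i) {
      from <- q_max - grid$q[i] + 1L   # common sample across candidates
      poly_dlm(x[from:n], y[from:n], q = grid$q[i], k = grid$k[i])
    })
  } else {
    if (is.null(formula) || is.null(data)) {
      if (!is.null(x) && !is.null(y)) {
        data <- data.frame(Y = y, X = x); formula <- Y ~ X
      } else stop("dlm search needs formula and data (or x and y)", call. = FALSE)
    }
    tab <- as_ts_table(data, frequency)
    pf <- parse_dlag_formula(formula, tab)
    grid <- data.frame(q = q_min:q_max)
    fits <- lapply(grid$q, function(q)
      finite_dlm(formula, ts_window(tab, q_max - q + 1L), q = q,
                 frequency = frequency))
  }
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    a <- accuracy_row(f$y, f$fitted.values)
    lb <- stats::Box.test(f$residuals, lag = min(10L, f$n_eff - 1L),
                          type = "Ljung-Box")
    cbind(grid[i, , drop = FALSE], n = f$n_eff, AIC = f$aic, BIC = f$bic,
          MASE = a$MASE, GMRAE = a$GMRAE, MBRAE = a$MBRAE,
          radj = f$adj.r.squared, LjungBox.p = lb$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ord <- if (criterion == "radj") order(-out$radj) else order(out[[criterion]])
  out[ord, , drop = FALSE]
}
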