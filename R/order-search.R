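#' Candidate grids for the bounds-test order search
#'
#' `full_search_grid()` enumerates every combination of per-predictor
#' short-run orders `p_j` in `0..max_p` with autoregressive order `q` in
#' `1..max_q` — `(max_p + 1)^k * max_q` rows. `two_stage_grids()` returns
#' the stage-1 grid (equal p across predictors, `(max_p + 1) * max_q` rows)
#' and a function giving the stage-2 grid `{0..p_star}^k` for a chosen
#' `p_star`.
#'
#' @param k number of predictors.
#' @param max_p,max_q search maxima.
#' @return `full_search_grid`: a data frame with columns `p1..pk, q`.
#' @export
full_search_grid <- function(k, max_p, max_q) {
  args <- c(rep(list(0:max_p), k), list(1:max_q))
  names(args) <- c(paste0("p", seq_len(k)), "q")
  expand.grid(args)
}

#' @rdname full_search_grid
#' @param p_star stage-1 selected common order (for the stage-2 grid).
#' @return `two_stage_grids`: list with `stage1` (columns `p, q`) and
#'   `stage2(p_star)` returning the `{0..p_star}^k` grid.
#' @export
two_stage_grids <- function(k, max_p, max_q) {
  list(stage1 = expand.grid(p = 0:max_p, q = 1:max_q),
       stage2 = function(p_star) {
         args <- rep(list(0:p_star), k)
         names(args) <- paste0("p", seq_len(k))
         expand.grid(args)
       })
}

#' Lag-order search for the ARDL bounds test
#'
#' Selects the short-run orders `(p_1, ..., p_k)` and autoregressive order
#' `q` of the conditional error-correction model by minimising an
#' information criterion or accuracy measure over a candidate grid — either
#' the exhaustive grid (`full_search = TRUE`) or the fast two-stage scheme:
#' stage 1 assumes all `p_j` equal and scans `(p, q)` over
#' `{0..max_p} x {1..max_q}`; stage 2 fixes the selected `q*` and scans the
#' per-predictor grid `{0..p*}^k`.
#'
#' All candidate CECMs are fitted on a common effective sample (trimmed to
#' the largest candidate's alignment) so criteria are comparable. Ties are
#' broken towards parsimony: smallest `sum(p) + q`, then smallest `q`, then
#' lexicographic `p`.
#'
#' @param formula model formula `Y ~ X1 + ... + Xk`.
#' @param data a [ts_table()], data frame or matrix.
#' @param max_p,max_q search maxima (`max_p >= 0`, `max_q >= 1`).
#' @param criterion `"AIC"`, `"BIC"`, `"MASE"` or `"GMRAE"`.
#' @param case deterministic-term case used for the candidate CECMs.
#' @param full_search exhaustive search instead of the two-stage scheme.
#' @param trace keep the full (orders, criterion) table.
#' @param frequency observations per cycle (metadata).
#' @return An object of class `"bounds_orders"`: `p_star` (named list),
#'   `q_star`, `criterion`, `value`, `n_models` (per stage), and `trace`
#'   when requested.
#' @examples
#' d <- simulate_ardl(sim_spec(n = 150, k = 2, p = 1, q = 1, seed = 8))
#' bounds_order_search(Y ~ X1 + X2, d, max_p = 2, max_q = 2,
#'                     criterion = "BIC")
#' @export
bounds_order_search <- function(formula, data, max_p = 10, max_q = 10,
                                criterion = c("AIC", "BIC", "MASE", "GMRAE"),
                                case = 3, full_search = FALSE, trace = FALSE,
                                frequency = 1) {
  criterion <- match.arg(criterion)
  max_p <- check_count(max_p, "max_p"); max_q <- check_count(max_q, "max_q")
  if (max_q < 1L) stop("max_q must be at least 1", call. = FALSE)
  tab <- as_ts_table(data, frequency)
  pf <- parse_dlag_formula(formula, tab)
  k <- length(pf$predictors)
  trim <- max(max_p, max_q) + 1L
  if (trim >= tab$n) stop("max orders too large for the series length", call. = FALSE)
  common_rows <- (trim + 1L):tab$n
  eval_cand <- function(pvec, q) {
    p <- stats::setNames(as.list(pvec), pf$predictors)
    fit <- try(build_cecm(formula, tab, p = p, q = q, case = case), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    # re-fit on the common sample so criteria are comparable across orders
    keep <- fit$bounds_info$rows %in% common_rows
    fit2 <- fit_ols(fit$X[keep, , drop = FALSE], fit$y[keep],
                    family = "cecm", has_intercept = fit$has_intercept)
    switch(criterion,
           AIC = fit2$aic, BIC = fit2$bic,
           MASE = accuracy_row(fit2$y, fit2$fitted.values)$MASE,
           GMRAE = accuracy_row(fit2$y, fit2$fitted.values)$GMRAE)
  }
  pick <- function(grid, values) {
    ok <- is.finite(values)
    if (!any(ok)) stop("all candidate models infeasible", call. = FALSE)
    if (any(!ok)) message(sum(!ok), " infeasible candidate(s) skipped")
    g <- grid[ok, , drop = FALSE]; v <- values[ok]
    pcols <- grep("^p", names(g))
    complexity <- rowSums(g[, pcols, drop = FALSE]) + g$q
    ord <- do.call(order, c(list(v, complexity, g$q),
                            unname(as.list(g[, pcols, drop = FALSE]))))
    list(row = g[ord[1L], , drop = FALSE], value = v[ord[1L]])
  }
  if (full_search) {
    grid <- full_search_grid(k, max_p, max_q)
    vals <- vapply(seq_len(nrow(grid)), function(i)
      eval_cand(unlist(grid[i, 1:k]), grid$q[i]), numeric(1))
    best <- pick(grid, vals)
    out <- list(p_star = stats::setNames(as.list(unlist(best$row[1:k])),
                                         pf$predictors),
                q_star = best$row$q, criterion = criterion, value = best$value,
                n_models = c(full = nrow(grid)),
                method = "full")
    if (trace) out$trace <- cbind(grid, value = vals)
  } else {
    gs <- two_stage_grids(k, max_p, max_q)
    g1 <- gs$stage1
    v1 <- vapply(seq_len(nrow(g1)), function(i)
      eval_cand(rep(g1$p[i], k), g1$q[i]), numeric(1))
    names(g1)[1L] <- "p1"   # uniform complexity bookkeeping in pick()
    complexity_grid <- data.frame(p1 = g1$p1 * k, q = g1$q)
    b1 <- pick(data.frame(p1 = g1$p1, q = g1$q), v1)
    p_star1 <- b1$row$p1; q_star <- b1$row$q
    g2 <- gs$stage2(p_star1)
    v2 <- vapply(seq_len(nrow(g2)), function(i)
      eval_cand(unlist(g2[i, ]), q_star), numeric(1))
    g2q <- cbind(g2, q = q_star)
    b2 <- pick(g2q, v2)
    out <- list(p_star = stats::setNames(as.list(unlist(b2$row[1:k])),
                                         pf$predictors),
                q_star = q_star, criterion = criterion, value = b2$value,
                n_models = c(stage1 = nrow(g1), stage2 = nrow(g2),
                             total = nrow(g1) + nrow(g2)),
                method = "two-stage")
    if (trace) out$trace <- list(stage1 = cbind(g1, value = v1),
                                 stage2 = cbind(g2q, value = v2))
  }
  class(out) <- "bounds_orders"
  out
}

#' @export
print.bounds_orders <- function(x, ...) {
  cat("Bounds-test order search (", x$method, ", criterion ", x$criterion,
      ")\n", sep = "")
  cat("p* =", paste(names(x$p_star), unlist(x$p_star), sep = "=",
                    collapse = ", "), "  q* =", x$q_star, "\n")
  cat("criterion value:", format(x$value, digits = 7), "\n")
  cat("models fitted:", paste(names(x$n_models), x$n_models, sep = "=",
                              collapse = ", "), "\n")
  invisible(x)
}
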