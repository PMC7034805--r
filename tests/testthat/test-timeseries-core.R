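test_that("lag matrix construction aligns rows to the contiguous tail", {
  expect_equal(unname(build_lag_matrix(c(1, 2, 3, 4), 0)), cbind(c(1, 2, 3, 4)))
  expect_equal(unname(build_lag_matrix(c(1, 2, 3, 4), 1)), cbind(c(1, 2, 3)))
  # hand enumeration: lags {0,2} on (1..5) -> rows (3,1),(4,2),(5,3)
  m <- build_lag_matrix(c(1, 2, 3, 4, 5), c(0, 2), "x")
  expect_equal(unname(m), cbind(c(3, 4, 5), c(1, 2, 3)))
  expect_equal(colnames(m), c("x.t", "x.2"))
  # exact invertibility: column lag-s at row r recovers series[r + maxlag - s]
  set.seed(1)
  s <- rnorm(30)
  lags <- c(0, 1, 3, 5)
  m <- build_lag_matrix(s, lags, "s")
  for (j in seq_along(lags))
    for (r in seq_len(nrow(m)))
      expect_identical(unname(m[r, j]), s[r + max(lags) - lags[j]])
})

test_that("lag matrix rejects empty and oversized lag sets", {
  expect_error(build_lag_matrix(1:5, integer(0)), "empty lag set")
  expect_error(build_lag_matrix(1:5, 5), "insufficient data")
})

test_that("first difference matches hand arithmetic and kills linear trends", {
  expect_equal(ts_difference(c(1, 1, 1)), c(0, 0))
  expect_equal(ts_difference(c(1, 3, 6, 10)), c(2, 3, 4))
  tt <- 3 + 0.7 * (1:25)
  expect_equal(ts_difference(tt), rep(0.7, 24))
  expect_error(ts_difference(5), "insufficient data")
})

test_that("fit_ols reproduces the normal-equations oracle and its summaries", {
  set.seed(11)
  X <- cbind(`(Intercept)` = 1, a = rnorm(30), b = rnorm(30))
  y <- 1 + 2 * X[, "a"] - 0.5 * X[, "b"] + rnorm(30)
  fit <- distlag:::fit_ols(X, y)
  expect_all_close(coef(fit), ols_oracle(X, y))
  # X' r = 0 on the retained columns
  expect_lt(max(abs(crossprod(X, residuals(fit)))), 1e-8)
  # fitted + residuals reproduce the response
  expect_all_close(fitted(fit) + residuals(fit), y, tol = 1e-10)
  # sigma, covariance and information criteria agree with lm conventions
  lmref <- lm(y ~ X[, -1])
  expect_equal(fit$sigma, summary(lmref)$sigma)
  expect_equal(unname(fit$aic), unname(AIC(lmref)))
  expect_equal(unname(fit$bic), unname(BIC(lmref)))
  expect_equal(fit$r.squared, summary(lmref)$r.squared)
  expect_lt(fit$aic, fit$bic)  # n_eff > e^2 here
  # covariance is positive semi-definite
  expect_gte(min(eigen(vcov(fit), only.values = TRUE)$values), -1e-10)
})

test_that("fit_ols degenerate cases: perfect fit, intercept-only, collinearity", {
  x <- seq_len(20)
  y <- 2 + 3 * x
  fit <- distlag:::fit_ols(cbind(`(Intercept)` = 1, x = x), y)
  expect_equal(fit$r.squared, 1)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  fit0 <- distlag:::fit_ols(cbind(`(Intercept)` = rep(1, 20)), y)
  expect_equal(unname(coef(fit0)), mean(y))
  expect_error(
    distlag:::fit_ols(cbind(`(Intercept)` = 1, x = x, x2 = 2 * x), y),
    "singular design.*x2")
})

test_that("effective-sample bookkeeping matches n - max_lag across families", {
  tab <- make_sealevel_shaped()
  expect_equal(finite_dlm(GMSL ~ LandOcean, tab, q = 7)$n_eff, 1588)
  expect_equal(finite_dlm(GMSL ~ -1 + LandOcean, tab, q = 6,
                          remove = list(LandOcean = c(0, 1, 2)))$n_eff, 1589)
  expect_equal(koyck_dlm(tab$values[, "LandOcean"], tab$values[, "GMSL"])$n_eff,
               1594)
  expect_equal(ardl_dlm(GMSL ~ LandOcean + SOI, tab, p = 2, q = 4,
                        remove = list(p = list(SOI = 2)))$n_eff, 1591)
})

test_that("ts_table validates names, finiteness and frequency", {
  expect_error(ts_table(cbind(a = 1:5, a = 1:5)), "duplicated")
  expect_error(ts_table(matrix(1:4, 2)), "name")
  tab <- ts_table(cbind(Y = c(1, NA, 3), X = 1:3))
  expect_error(distlag:::ts_get(tab, "Y"), "missing")
  expect_error(ts_table(cbind(Y = 1:3), frequency = 0), "frequency")
})
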