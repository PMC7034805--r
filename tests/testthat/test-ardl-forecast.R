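test_that("ARDL degrees of freedom track removals on the declared design", {
  tab <- make_sealevel_shaped()
  f1 <- ardl_dlm(GMSL ~ LandOcean + SOI, tab, p = 2, q = 4,
                 remove = list(p = list(SOI = 2)))
  expect_equal(length(coef(f1)), 10)
  expect_equal(f1$df_resid, 1581)
  f2 <- ardl_dlm(GMSL ~ LandOcean + SOI, tab, p = 2, q = 4,
                 remove = list(p = list(LandOcean = 1, SOI = c(1, 2))))
  expect_equal(length(coef(f2)), 8)
  expect_equal(f2$df_resid, 1583)
  expect_equal(names(coef(f2)),
               c("(Intercept)", "LandOcean.t", "LandOcean.2", "SOI.t",
                 paste0("GMSL.", 1:4)))
})

test_that("ARDL coefficients equal an OLS oracle on a hand-built design", {
  tab <- make_table(40, k = 1, seed = 31)
  y <- tab$values[, "Y"]; x <- tab$values[, "X1"]
  fit <- ardl_dlm(Y ~ X1, tab, p = 1, q = 1)
  rows <- 2:40
  X <- cbind(1, x[rows], x[rows - 1], y[rows - 1])
  expect_all_close(coef(fit), ols_oracle(X, y[rows]))
})

test_that("constant model forecasts its intercept at every step", {
  tab <- ts_table(cbind(Y = rep(4.5, 30), X1 = rnorm(30)))
  fit <- finite_dlm(Y ~ X1, tab, q = 2)
  fc <- forecast(fit, x_new = matrix(rnorm(3), 1, 3), h = 3)
  expect_all_close(fc$mean, rep(4.5, 3), tol = 1e-8)
})

test_that("pure AR forecast follows the closed-form gamma^h recursion", {
  g <- 0.8
  y <- g^(1:40)
  tab <- ts_table(cbind(Y = y, X1 = rnorm(40)))
  fit <- ardl_dlm(Y ~ -1 + X1, tab, p = 0, q = 1,
                  remove = list(p = list(X1 = 0)))
  expect_equal(unname(coef(fit)), g, tolerance = 1e-10)
  fc <- forecast(fit, x_new = matrix(0, 1, 4), h = 4)
  expect_all_close(fc$mean, g^(1:4) * y[40], tol = 1e-10)
})

test_that("two-step ARDL(1,1) recursion matches a hand-computed oracle", {
  # fixed 5-point history, coefficients set by an exact-fit construction
  mu0 <- 0.3; b0 <- 1.2; b1 <- -0.4; g1 <- 0.6
  set.seed(32)
  x <- rnorm(7)
  y <- numeric(7); y[1] <- 0.5
  for (t in 2:7) y[t] <- mu0 + b0 * x[t] + b1 * x[t - 1] + g1 * y[t - 1]
  tab <- ts_table(cbind(Y = y, X1 = x))
  fit <- ardl_dlm(Y ~ X1, tab, p = 1, q = 1)
  expect_all_close(coef(fit), c(mu0, b0, b1, g1), tol = 1e-8)
  xn <- c(0.25, -0.75)
  f1 <- mu0 + b0 * xn[1] + b1 * x[7] + g1 * y[7]
  f2 <- mu0 + b0 * xn[2] + b1 * xn[1] + g1 * f1
  fc <- forecast(fit, x_new = matrix(xn, 1, 2), h = 2)
  expect_all_close(fc$mean, c(f1, f2), tol = 1e-10)
})

test_that("interval forecasts are seed-reproducible and widen with horizon", {
  d <- simulate_ardl(sim_spec(n = 300, k = 1, p = 1, q = 1,
                              gamma = 0.9, seed = 33))
  fit <- ardl_dlm(Y ~ X1, d, p = 1, q = 1)
  xn <- matrix(0, 1, 6)
  fc1 <- forecast(fit, x_new = xn, h = 6, interval = TRUE, nSim = 300, seed = 9)
  fc2 <- forecast(fit, x_new = xn, h = 6, interval = TRUE, nSim = 300, seed = 9)
  expect_identical(fc1$mean, fc2$mean)
  expect_identical(fc1$lower, fc2$lower)
  expect_identical(fc1$upper, fc2$upper)
  width <- fc1$upper - fc1$lower
  expect_true(all(fc1$lower < fc1$upper))
  expect_gt(width[6], width[1])  # shocks feed the AR recursion
})

test_that("forecast validates the x_new shape", {
  d <- simulate_ardl(sim_spec(n = 100, k = 2, p = 1, q = 1, seed = 34))
  fit <- ardl_dlm(Y ~ X1 + X2, d, p = 1, q = 1)
  expect_error(forecast(fit, x_new = matrix(0, 1, 3), h = 3), "2 x 3")
  expect_error(forecast(fit, h = 2), "x_new is required")
})

test_that("generic accessors behave identically across model families", {
  tab <- make_table(100, k = 1, seed = 35)
  x <- tab$values[, "X1"]; y <- tab$values[, "Y"]
  fits <- list(finite = finite_dlm(Y ~ X1, tab, q = 2),
               poly = poly_dlm(x, y, q = 2, k = 1),
               koyck = koyck_dlm(x, y),
               ardl = ardl_dlm(Y ~ X1, tab, p = 1, q = 1))
  for (f in fits) {
    expect_equal(length(residuals(f)), f$n_eff)
    expect_equal(length(fitted(f)), f$n_eff)
    expect_all_close(fitted(f) + residuals(f), f$y, tol = 1e-8)
    expect_s3_class(summary(f), "summary.dlag")
    expect_true(is.finite(AIC(f)) && is.finite(BIC(f)) && AIC(f) < BIC(f))
  }
})
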