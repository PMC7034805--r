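test_that("accuracy measures match hand computation", {
  f <- fake_fit(c(1, 2, 3, 4), c(1, 2, 3, 5))
  g <- gof(m1 = f, m2 = f)
  expect_equal(g$MAE[1], 0.25)
  expect_equal(g$MSE[1], 0.25)
  # benchmark-aligned errors (0,0,-1) vs naive errors (1,1,1): MASE = 1/3
  expect_equal(g$MASE[1], (1 / 3) / 1)
  # perfect fit zeroes the absolute measures
  p <- gof(a = fake_fit(c(1, 2, 4), c(1, 2, 4)),
           b = fake_fit(c(1, 2, 4), c(1, 2, 5)))
  expect_equal(unname(unlist(p[1, c("MAE", "MSE", "MAPE", "MASE")])),
               c(0, 0, 0, 0))
})

test_that("equal model and benchmark errors pin BRAE at 1/2", {
  set.seed(41)
  y <- cumsum(rnorm(30))
  naive <- fake_fit(y[-1], y[-30])   # model errors == benchmark errors
  g <- gof(naive = naive, other = fake_fit(y[-1], y[-1] + 0.5))
  expect_equal(g["naive", "MBRAE"], 0.5)
  expect_equal(g["naive", "UMBRAE"], 1)
  # naive forecast scores MASE exactly 1 on its own sample
  expect_equal(g["naive", "MASE"], 1)
})

test_that("GMRAE <= MRAE and UMBRAE is monotone in MBRAE", {
  set.seed(42)
  for (r in 1:10) {
    y <- cumsum(rnorm(40))
    f <- y + rnorm(40, 0, 0.7)
    g <- gof(a = fake_fit(y, f), b = fake_fit(y, y + rnorm(40)))
    expect_lte(g$GMRAE[1], g$MRAE[1] + 1e-12)
  }
  u <- function(m) m / (1 - m)
  ms <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(u(ms)) > 0))
})

test_that("MBRAE columns appear only with two or more models", {
  f <- fake_fit(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.4))
  expect_false("MBRAE" %in% names(gof(single = f)))
  expect_true(all(c("MBRAE", "UMBRAE") %in% names(gof(a = f, b = f))))
})

test_that("sort_score orders ascending with deterministic tie-breaks", {
  tab <- data.frame(n = c(10, 10, 10), MASE = c(3, 1, 2),
                    row.names = c("mA", "mB", "mC"))
  out <- sort_score(tab, "MASE")
  expect_equal(rownames(out), c("mB", "mC", "mA"))
  expect_equal(rownames(sort_score(tab[1, , drop = FALSE], "MASE")), "mA")
  # brute-force comparison-sort oracle on random rows
  set.seed(43)
  big <- data.frame(n = 1:20, MASE = sample(c(runif(15), rep(0.5, 5))),
                    row.names = sprintf("m%02d", 1:20))
  out <- sort_score(big, "MASE")
  oracle <- big[order(big$MASE, rownames(big)), ]
  expect_identical(rownames(out), rownames(oracle))
  expect_error(sort_score(big, "RMSLE"), "valid scores")
})

test_that("finite-order search table equals fitting each model individually", {
  tab <- make_table(80, k = 1, seed = 44)
  res <- search_finite_order(Y ~ X1, tab, q_min = 1, q_max = 4,
                             criterion = "BIC")
  expect_equal(nrow(res), 4)
  expect_true(all(res$n == 80 - 4))  # candidates share the common sample
  for (i in seq_len(nrow(res))) {
    q <- res$q[i]
    trimmed <- tab$values[(4 - q + 1):80, ]  # oracle: align then fit alone
    f <- finite_dlm(Y ~ X1, ts_table(trimmed, frequency = 12), q = q)
    expect_equal(res$AIC[i], f$aic)
    expect_equal(res$BIC[i], f$bic)
    expect_equal(res$radj[i], f$adj.r.squared)
  }
  expect_true(all(diff(res$BIC) >= 0))
  single <- search_finite_order(Y ~ X1, tab, q_min = 2, q_max = 2)
  expect_equal(nrow(single), 1)
  # poly search enumerates k <= q
  x <- tab$values[, "X1"]; y <- tab$values[, "Y"]
  pres <- search_finite_order(x = x, y = y, q_min = 1, q_max = 3,
                              model_type = "poly", criterion = "AIC")
  expect_equal(nrow(pres), 2 + 3 + 4)
  expect_true(all(pres$k <= pres$q))
})

test_that("BIC search recovers the true finite lag order under strong signal", {
  q_true <- 3
  hits <- 0L
  reps <- 40
  for (r in seq_len(reps)) {
    set.seed(5000 + r)
    n <- 300
    x <- rnorm(n)
    y <- numeric(n)
    for (t in (q_true + 1):n)
      y[t] <- 1 + sum(c(2, 1.5, 1, 0.8) * x[t - (0:q_true)]) + rnorm(1, 0, 0.5)
    tab <- ts_table(cbind(Y = y, X1 = x))
    res <- search_finite_order(Y ~ X1, tab, q_min = 1, q_max = 6,
                               criterion = "BIC")
    hits <- hits + (res$q[1] == q_true)
  }
  expect_gte(hits / reps, 0.90)
})
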