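# Shared fixtures: all data is generated in code, nothing is stored on disk.

# small deterministic table with named series for structural checks
make_table <- function(n = 60, k = 2, seed = 42,
                       names = c("Y", paste0("X", seq_len(k)))) {
  set.seed(seed)
  vals <- matrix(rnorm(n * (k + 1)), n, k + 1)
  colnames(vals) <- names
  ts_table(vals, frequency = 12)
}

# length-1595 table matching the worked example's series names
make_sealevel_shaped <- function(seed = 7) {
  set.seed(seed)
  ts_table(cbind(GMSL = cumsum(rnorm(1595, 0, 0.5)),
                 LandOcean = rnorm(1595),
                 SOI = rnorm(1595)),
           frequency = 12)
}

# brute-force OLS via the normal equations (independent oracle)
ols_oracle <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))

# minimal model-like object for accuracy-measure tests
fake_fit <- function(actual, fitted) {
  structure(list(y = actual, fitted.values = fitted,
                 n_eff = length(actual)), class = "dlag")
}

expect_all_close <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(unname(a) - unname(b))), tol)
}
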