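#' Rolling Pearson correlation
#'
#' Trailing-window correlation: element `i` is the Pearson correlation of
#' the two series over the window ending at observation `i + width - 1`.
#' Windows in which either series is constant yield `NA` (recorded and
#' excluded from summary statistics downstream).
#'
#' @param x,y numeric series of equal length.
#' @param width window length (>= 3).
#' @return vector of length `length(x) - width + 1`.
#' @export
rolling_correlation <- function(x, y, width) {
  width <- check_count(width, "width")
  if (width < 3L) stop("width must be at least 3", call. = FALSE)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (width > n) stop("width exceeds the series length", call. = FALSE)
  # windowed moments via cumulative sums
  sx <- roll_sum(x, width);  sy <- roll_sum(y, width)
  sxx <- roll_sum(x^2, width); syy <- roll_sum(y^2, width)
  sxy <- roll_sum(x * y, width)
  vx <- sxx - sx^2 / width
  vy <- syy - sy^2 / width
  cv <- sxy - sx * sy / width
  denom2 <- vx * vy
  out <- ifelse(denom2 > 0, cv / sqrt(pmax(denom2, 0)), NA_real_)
  # guard tiny negative variances from floating cancellation
  out[vx <= .Machine$double.eps * width | vy <= .Machine$double.eps * width] <- NA_real_
  pmin(pmax(out, -1), 1)
}

#' Monte Carlo percentile limits for rolling-correlation variability
#'
#' Simulates `N` pairs of bivariate Gaussian white-noise series of length
#' `n` with correlation `cor` (lower-triangular transform of independent
#' normals), computes the standard deviation of the width-`width` rolling
#' correlations of each pair, and returns the requested empirical
#' percentiles of that null distribution.
#'
#' @param n series length.
#' @param cor target correlation of the null pair (`|cor| < 1`).
#' @param width rolling window length (scalar or vector).
#' @param N Monte Carlo replicates (>= 100).
#' @param percentiles probabilities of the returned limits.
#' @param seed RNG seed.
#' @return data frame with one row per width and one column per percentile.
#' @export
sd_percentiles <- function(n, cor = 0, width = 5, N = 500,
                           percentiles = c(0.05, 0.95), seed = NULL) {
  if (abs(cor) >= 1) stop("|cor| must be below 1", call. = FALSE)
  if (N < 100) stop("N must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  width <- vapply(width, check_count, integer(1), what = "width")
  sds <- matrix(NA_real_, N, length(width))
  for (r in seq_len(N)) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    a <- z1
    b <- cor * z1 + sqrt(1 - cor^2) * z2
    for (j in seq_along(width))
      sds[r, j] <- stats::sd(rolling_correlation(a, b, width[j]), na.rm = TRUE)
  }
  qs <- matrix(apply(sds, 2, stats::quantile, probs = percentiles,
                     na.rm = TRUE),
               nrow = length(percentiles))
  out <- as.data.frame(t(qs))
  names(out) <- paste0(format(100 * percentiles, trim = TRUE), "%")
  cbind(width = width, out)
}

#' Monte Carlo significance test of signal versus correlated white noise
#'
#' For each window width, computes the rolling-correlation path of the two
#' series and its standard deviation, then compares that SD with the
#' `(1 - level)` and `level` one-tailed percentile limits of the SD of
#' rolling correlations between two white-noise series sharing the
#' empirical Pearson correlation. An SD outside the limits flags a
#' significant signal (more or less variable than noise). The width-averaged
#' path (on the overlap common to every width) is smoothed with a running
#' median for plotting, with a `level` confidence band for its mean.
#'
#' @param x,y numeric series of equal length.
#' @param widths vector of window lengths (widths exceeding the series
#'   length are skipped with a notice).
#' @param level test/confidence level (default 0.95).
#' @param N Monte Carlo replicates for the null percentiles.
#' @param seed RNG seed (recorded).
#' @param runmed_k running-median span (odd, default 3).
#' @return Object of class `"signal_test"`: `rolcor` (per-width paths),
#'   `avg_raw`, `avg_filtered`, `band` (mean and confidence limits),
#'   `raw_cor`, `sd_limits`, `test` (width, SD, upper, lower, flag), `N`,
#'   `level`, `seed`.
#' @examples
#' set.seed(1)
#' x <- rnorm(80); y <- 0.6 * x + rnorm(80)
#' st <- signal_test(x, y, widths = c(5, 9), N = 200, seed = 2)
#' st$test
#' @export
signal_test <- function(x, y, widths = c(3, 5, 7, 11), level = 0.95,
                        N = 500, seed = NULL, runmed_k = 3) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  ok <- widths <= n
  if (!all(ok)) {
    message("skipping width(s) ", paste(widths[!ok], collapse = ", "),
            " exceeding the series length")
    widths <- widths[ok]
  }
  if (length(widths) == 0L) stop("no usable widths", call. = FALSE)
  widths <- sort(as.integer(widths))
  paths <- lapply(widths, function(w) rolling_correlation(x, y, w))
  names(paths) <- paste0("w", widths)
  sds <- vapply(paths, stats::sd, numeric(1), na.rm = TRUE)
  # overlap covered by every width: original indices max(widths)..n
  wmax <- max(widths)
  aligned <- vapply(seq_along(widths), function(j)
    paths[[j]][(wmax - widths[j] + 1L):(n - widths[j] + 1L)],
    numeric(n - wmax + 1L))
  avg_raw <- rowMeans(aligned)
  kk <- max(3L, runmed_k + (1L - runmed_k %% 2L))  # force odd
  avg_filtered <- if (length(avg_raw) >= kk)
    stats::runmed(avg_raw, kk) else avg_raw
  raw_cor <- stats::cor(x, y)
  lim <- sd_percentiles(n, raw_cor, widths, N = N,
                        percentiles = c(1 - level, level), seed = seed)
  lower <- lim[[2L]]; upper <- lim[[3L]]
  test <- data.frame(width = widths, SDrolCor = unname(sds),
                     upper = upper, lower = lower,
                     significant = sds > upper | sds < lower)
  names(test)[3:4] <- paste0(format(100 * c(level, 1 - level), trim = TRUE), "%")
  mu <- mean(avg_filtered)
  se <- stats::sd(avg_filtered) / sqrt(length(avg_filtered))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    widths = widths, rolcor = paths, avg_raw = avg_raw,
    avg_filtered = avg_filtered,
    band = c(mean = mu, lower = mu - zq * se, upper = mu + zq * se),
    raw_cor = raw_cor, sd_limits = lim, test = test,
    N = N, level = level, seed = seed), class = "signal_test")
}

#' @export
print.signal_test <- function(x, digits = 7, ...) {
  cat("Rolling-correlation signal test (level ", x$level, ", N = ", x$N,
      ")\nraw correlation: ", format(x$raw_cor, digits = digits), "\n\n",
      sep = "")
  print(x$test, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.signal_test <- function(x, ...) {
  n_over <- length(x$avg_filtered)
  idx <- seq_len(n_over) + max(x$widths) - 1L
  graphics::plot(idx, x$avg_filtered, type = "n", ylim = c(-1, 1),
                 xlab = "time", ylab = "rolling correlation", ...)
  for (j in seq_along(x$rolcor)) {
    p <- x$rolcor[[j]]
    graphics::lines(seq_along(p) + x$widths[j] - 1L, p, col = "grey70")
  }
  graphics::lines(idx, x$avg_filtered, lwd = 2)
  graphics::abline(h = x$band["mean"], lty = 1)
  graphics::abline(h = x$band[c("lower", "upper")], lty = 2, col = 2)
  invisible(x)
}
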