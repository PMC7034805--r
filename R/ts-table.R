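#' Multivariate time-series table
#'
#' A light container for the observed series entering distributed-lag models:
#' a numeric matrix with one column per series plus frequency metadata. All
#' lag arithmetic in the package is done in whole observation steps; the
#' `start`/`frequency` fields are carried for labelling only, never for
#' calendar arithmetic.
#'
#' @param values numeric matrix or data frame, one column per series.
#' @param frequency observations per cycle (12 for monthly, 4 for quarterly).
#' @param start time origin, e.g. `c(1885, 7)`; kept as metadata.
#' @param labels optional character vector of row labels (e.g. dates read
#'   from a CSV date column); excluded from the numeric matrix.
#'
#' @return An object of class `"ts_table"`: a list with `values` (numeric
#'   matrix), `names`, `n`, `frequency`, `start`, `labels`.
#' @examples
#' tab <- ts_table(data.frame(Y = rnorm(20), X = rnorm(20)), frequency = 12)
#' tab$n
#' @export
ts_table <- function(values, frequency = 1, start = 1, labels = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, ncol = 1L)
  if (!is.numeric(values))
    stop("ts_table: 'values' must be numeric; non-numeric columns found", call. = FALSE)
  nm <- colnames(values)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("ts_table: every series needs a name (column names)", call. = FALSE)
  if (anyDuplicated(nm))
    stop("ts_table: duplicated series name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency < 1)
    stop("ts_table: 'frequency' must be a single number >= 1", call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(values))
    stop("ts_table: 'labels' length must equal the number of rows", call. = FALSE)
  structure(
    list(values = values, names = nm, n = nrow(values),
         frequency = as.numeric(frequency), start = start, labels = labels),
    class = "ts_table")
}

#' @export
print.ts_table <- function(x, ...) {
  cat("Time-series table: ", x$n, " observations of ", length(x$names),
      " series (frequency ", x$frequency, ")\n", sep = "")
  cat("Series:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

# window of rows from:n as a new ts_table (used to align search candidates)
ts_window <- function(tab, from) {
  ts_table(tab$values[from:tab$n, , drop = FALSE], frequency = tab$frequency,
           start = tab$start,
           labels = if (!is.null(tab$labels)) tab$labels[from:tab$n])
}

# coerce data.frame / matrix / ts_table inputs used by fitting functions
as_ts_table <- function(data, frequency = 1) {
  if (inherits(data, "ts_table")) return(data)
  ts_table(data, frequency = frequency)
}

ts_get <- function(tab, name) {
  if (!name %in% tab$names)
    stop("series '", name, "' not found in the data (have: ",
         paste(tab$names, collapse = ", "), ")", call. = FALSE)
  v <- tab$values[, name]
  if (anyNA(v) || any(!is.finite(v)))
    stop("series '", name, "' contains missing or non-finite values inside ",
         "the modelling window; silent row deletion would break lag alignment",
         call. = FALSE)
  v
}

#' Read a time-series table from CSV
#'
#' Expects a header row of series names and numeric columns; an optional
#' date/label column may be declared with `date_col` and is retained as row
#' labels but excluded from the numeric matrix. The frequency is supplied,
#' never inferred from dates.
#'
#' @param path CSV file path.
#' @param frequency observations per cycle.
#' @param date_col optional name (or index) of a non-numeric date column.
#' @return A [ts_table()].
#' @export
read_ts_csv <- function(path, frequency = 1, date_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty file: ", path, call. = FALSE)
  nm <- names(df)
  if (anyDuplicated(nm))
    stop("duplicated column name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  labels <- NULL
  if (!is.null(date_col)) {
    if (is.numeric(date_col)) date_col <- nm[date_col]
    if (!date_col %in% nm) stop("date column '", date_col, "' not found", call. = FALSE)
    labels <- as.character(df[[date_col]])
    df[[date_col]] <- NULL
  }
  for (j in names(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric cell(s) in column '", j, "', row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
      df[[j]] <- vn
    }
  }
  ts_table(df, frequency = frequency, labels = labels)
}

#' Build a lagged design matrix from one series
#'
#' Rows are aligned to the contiguous tail of the series: the first
#' `max(lags)` observations are dropped (no padding or imputation), so row
#' `r` of the result corresponds to original time index `r + max(lags)`, and
#' the column for lag `s` holds `series[t - s]`.
#'
#' @param series numeric vector.
#' @param lags set of non-negative integer lags; columns are returned in
#'   ascending lag order.
#' @param name series name used for column labels: `"<name>.t"` for lag 0 and
#'   `"<name>.s"` for lag `s >= 1`.
#' @return numeric matrix with `length(series) - max(lags)` rows.
#' @examples
#' build_lag_matrix(c(1, 2, 3, 4, 5), c(0, 2), "x")
#' @export
build_lag_matrix <- function(series, lags, name = "x") {
  if (length(lags) == 0L)
    stop("empty lag set for '", name, "'", call. = FALSE)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 0)) stop("negative lag for '", name, "'", call. = FALSE)
  n <- length(series)
  if (max(lags) >= n)
    stop("insufficient data: max lag ", max(lags), " >= series length ", n,
         call. = FALSE)
  mx <- max(lags)
  out <- vapply(lags, function(s) series[(mx + 1L - s):(n - s)],
                numeric(n - mx))
  out <- matrix(out, nrow = n - mx)
  colnames(out) <- lag_labels(name, lags)
  out
}

lag_labels <- function(name, lags) {
  ifelse(lags == 0L, paste0(name, ".t"), paste0(name, ".", lags))
}

#' First difference of a series
#'
#' @param series numeric vector of length at least 2.
#' @return vector of length `length(series) - 1`, element `t` equal to
#'   `series[t + 1] - series[t]`.
#' @export
ts_difference <- function(series) {
  n <- length(series)
  if (n < 2L) stop("insufficient data: need at least 2 observations to difference",
                   call. = FALSE)
  series[-1L] - series[-n]
}
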