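#' Construct a uniformly sampled glucose series
#'
#' `glucose_series` is the package's central data object: a uniformly
#' sampled continuous glucose monitoring (CGM) signal in mmol/L. Timestamps
#' are minutes since series start and must advance by exactly
#' `sampling_period` between consecutive samples (tolerance 1e-9); series
#' with measurement gaps must first be cut into uniform segments with
#' [segment_by_gaps()].
#'
#' @param times Numeric vector, minutes since series start, strictly
#'   increasing with constant spacing `sampling_period`.
#' @param values Numeric vector of glucose readings in mmol/L; finite and
#'   positive.
#' @param sampling_period Sampling period in minutes (default 5, i.e. 288
#'   samples/day as delivered by standard CGM sensors).
#' @param subject_id Opaque subject label.
#' @return An object of class `glucose_series`.
#' @examples
#' s <- glucose_series(seq(0, 45, by = 5), rep(7, 10))
#' length(s$values)
#' @export
glucose_series <- function(times, values, sampling_period = 5,
                           subject_id = "synthetic") {
  s <- structure(
    list(times = as.numeric(times), values = as.numeric(values),
         sampling_period = as.numeric(sampling_period),
         subject_id = subject_id),
    class = "glucose_series")
  validate_glucose_series(s)
  s
}

validate_glucose_series <- function(s) {
  if (length(s$times) != length(s$values))
    stop("times and values differ in length")
  if (length(s$values) == 0)
    stop("glucose series must contain at least one sample")
  if (!all(is.finite(s$values)) || any(s$values <= 0))
    stop("glucose values must be finite and > 0 (mmol/L)")
  if (length(s$times) > 1) {
    d <- diff(s$times)
    if (any(d <= 0)) stop("timestamps must be strictly increasing")
    if (any(abs(d - s$sampling_period) > 1e-9))
      stop("sampling is not uniform at period ", s$sampling_period,
           " min; segment the series around gaps first")
  }
  invisible(s)
}

#' @export
print.glucose_series <- function(x, ...) {
  cat(sprintf(
    "<glucose_series> subject '%s': %d samples @ %g min (%.1f h), %.2f-%.2f mmol/L\n",
    x$subject_id, length(x$values), x$sampling_period,
    diff(range(x$times)) / 60, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.glucose_series <- function(x) length(x$values)

#' Read a CGM series from CSV
#'
#' Expects the package CSV dialect: header `time_min,glucose`, comma
#' separator, decimal point. Values given in mg/dl are converted to the
#' internal canonical unit mmol/L at this boundary (factor 18.0182).
#'
#' @param path File path.
#' @param value_unit Unit of the glucose column: `"mmol/L"` (default) or
#'   `"mg/dl"`.
#' @param sampling_period Expected sampling period in minutes.
#' @param subject_id Subject label to attach.
#' @return A [glucose_series()].
#' @export
read_cgm_csv <- function(path, value_unit = c("mmol/L", "mg/dl"),
                         sampling_period = 5, subject_id = basename(path)) {
  value_unit <- match.arg(value_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty CGM file: ", path)
  start <- if (grepl("^\\s*time", lines[1], ignore.case = TRUE)) 2L else 1L
  if (length(lines) < start) stop("CGM file has a header but no data rows: ", path)
  n <- length(lines) - start + 1L
  times <- numeric(n); values <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[start + i - 1L], ",", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stop("malformed row at line ", start + i - 1L, ": expected 'time,glucose'")
    t <- suppressWarnings(as.numeric(fields[1]))
    v <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(t) || is.na(v))
      stop("malformed row at line ", start + i - 1L, ": non-numeric field")
    times[i] <- t; values[i] <- v
  }
  if (n > 1 && any(diff(times) <= 0))
    stop("timestamps in ", path, " are not strictly increasing")
  if (value_unit == "mg/dl") values <- mgdl_to_mmol(values)
  glucose_series(times, values, sampling_period = sampling_period,
                 subject_id = subject_id)
}

#' Write a CGM series to CSV
#'
#' Writes the package CSV dialect (`time_min,glucose` header) at full double
#' precision, so [read_cgm_csv()] reproduces the series exactly.
#'
#' @param series A [glucose_series()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cgm_csv <- function(series, path) {
  validate_glucose_series(series)
  lines <- c("time_min,glucose",
             sprintf("%.17g,%.17g", series$times, series$values))
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write CGM file ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Cut a raw CGM trace into uniformly sampled segments around gaps
#'
#' Real sensor traces contain measurement gaps; autoregressive windows must
#' never straddle them. The trace is split wherever consecutive timestamps
#' differ by more than `max_gap` minutes, and segments too short to yield a
#' single training window (fewer than `min_length` samples) are discarded —
#' padding would fabricate data. Within each retained segment the spacing
#' must equal `sampling_period` exactly (tolerance 1e-9); segment timestamps
#' are rebased to start at 0.
#'
#' @param times Raw timestamps in minutes, strictly increasing.
#' @param values Raw glucose values in mmol/L.
#' @param sampling_period Nominal sampling period in minutes (default 5).
#' @param max_gap Largest tolerated step between consecutive samples, in
#'   minutes. Default `2 * sampling_period`: one missed reading is tolerable,
#'   more breaks the tap structure.
#' @param min_length Shortest segment worth keeping (default 40 = one
#'   20-input/20-output training window).
#' @param subject_id Label attached to each segment.
#' @return List of [glucose_series()] segments (possibly empty).
#' @export
segment_by_gaps <- function(times, values, sampling_period = 5,
                            max_gap = 2 * sampling_period, min_length = 40,
                            subject_id = "synthetic") {
  stopifnot(length(times) == length(values))
  if (length(times) == 0) return(list())
  if (any(diff(times) <= 0)) stop("timestamps must be strictly increasing")
  breaks <- which(diff(times) > max_gap)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(times))
  segs <- list()
  for (j in seq_along(starts)) {
    idx <- starts[j]:ends[j]
    if (length(idx) < min_length) next
    segs[[length(segs) + 1L]] <- glucose_series(
      times[idx] - times[idx[1]], values[idx],
      sampling_period = sampling_period, subject_id = subject_id)
  }
  segs
}

#' Split a series into a leading test block and a training remainder
#'
#' The evaluation protocol assigns the first `n_test` samples of the
#' assembled data to testing/validation and everything after to training
#' (e.g. 500 test / 4416 training samples out of 4916).
#'
#' @param series A [glucose_series()].
#' @param n_test Number of leading samples for the test set (default 500).
#' @return List with elements `test` and `train`, both [glucose_series()].
#' @export
split_first_n <- function(series, n_test = 500) {
  validate_glucose_series(series)
  n <- length(series$values)
  if (n_test <= 0 || n_test >= n)
    stop("n_test must satisfy 0 < n_test < series length (", n, ")")
  take <- function(idx) glucose_series(
    series$times[idx] - series$times[idx[1]], series$values[idx],
    sampling_period = series$sampling_period, subject_id = series$subject_id)
  list(test = take(seq_len(n_test)), train = take((n_test + 1):n))
}
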