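#' Centered moving-average smoothing with shrinking endpoint windows
#'
#' Smooths a glucose sequence with a centered moving average of odd `span`
#' (default 11 samples = 55 min at 5-min sampling). Near the ends the window
#' shrinks symmetrically: point `i` (1-based) averages over
#' `2 * min(i - 1, n - i) + 1` samples capped at `span`, so the first and
#' last points are returned unchanged. Smoothing the CGM signal before
#' training reduces the lag between predicted and observed glucose.
#'
#' @param values Numeric sequence (mmol/L).
#' @param span Odd window width >= 1 (default 11).
#' @return Smoothed sequence, same length as input.
#' @examples
#' moving_average_smooth(c(1, 2, 6), span = 3)  # c(1, 3, 6)
#' @export
moving_average_smooth <- function(values, span = 11) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (span < 1 || span %% 2 == 0) stop("span must be an odd positive integer")
  n <- length(values)
  if (span == 1 || n == 1) return(values)
  half <- (span - 1) / 2
  out <- numeric(n)
  cs <- c(0, cumsum(values))
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    out[i] <- (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
  }
  out
}

#' Smooth a glucose series in place
#'
#' Applies [moving_average_smooth()] to the values of a [glucose_series()].
#' Smoothing is always per segment, never across gap boundaries.
#'
#' @param series A [glucose_series()].
#' @param span Odd window width (default 11).
#' @return The smoothed [glucose_series()].
#' @export
smooth_series <- function(series, span = 11) {
  validate_glucose_series(series)
  glucose_series(series$times, moving_average_smooth(series$values, span),
                 sampling_period = series$sampling_period,
                 subject_id = series$subject_id)
}

#' Cut sliding training windows from a segment
#'
#' Each window is a contiguous `n_in + n_out` sample slice: the first `n_in`
#' samples are the network inputs, the next `n_out` the targets. Window
#' starts advance by `stride` samples. With the defaults (20 in, 20 out)
#' each window is the 40-sample training unit used for open-loop training
#' toward the 100-minute horizon.
#'
#' @param segment A [glucose_series()] (already smoothed).
#' @param n_in Number of input samples (default 20).
#' @param n_out Number of target samples (default 20).
#' @param stride Start-to-start step in samples (default 1, making maximal
#'   use of the training data).
#' @return List of windows, each `list(inputs, targets, origin_index)` with
#'   `origin_index` the 1-based position of the first input sample; empty
#'   list if the segment is shorter than `n_in + n_out`.
#' @export
make_windows <- function(segment, n_in = 20, n_out = 20, stride = 1) {
  validate_glucose_series(segment)
  stopifnot(n_in >= 1, n_out >= 1, stride >= 1)
  v <- segment$values
  L <- length(v)
  if (L < n_in + n_out) return(list())
  starts <- seq(1L, L - n_in - n_out + 1L, by = stride)
  lapply(starts, function(s) {
    list(inputs = v[s:(s + n_in - 1)],
         targets = v[(s + n_in):(s + n_in + n_out - 1)],
         origin_index = s)
  })
}

#' Fit an affine scaler mapping a data range onto [-1, 1]
#'
#' The tanh hidden units of the network want inputs and targets in a bounded
#' range; the scaler maps `[lo, hi]` (the min/max of the training values)
#' affinely onto `[-1, 1]`. Fit on training data only — fitting on test data
#' would leak.
#'
#' @param values Training glucose values (at least 2 distinct).
#' @return A `glucose_scaler` object with fields `lo` and `hi`.
#' @export
fit_scaler <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  lo <- min(values); hi <- max(values)
  if (hi <= lo) stop("cannot fit scaler on constant input")
  structure(list(lo = lo, hi = hi), class = "glucose_scaler")
}

#' @rdname fit_scaler
#' @param s A fitted `glucose_scaler`.
#' @export
apply_scaler <- function(s, values) {
  stopifnot(inherits(s, "glucose_scaler"))
  2 * (values - s$lo) / (s$hi - s$lo) - 1
}

#' @rdname fit_scaler
#' @param scaled Values on the [-1, 1] scale.
#' @export
invert_scaler <- function(s, scaled) {
  stopifnot(inherits(s, "glucose_scaler"))
  (scaled + 1) / 2 * (s$hi - s$lo) + s$lo
}
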