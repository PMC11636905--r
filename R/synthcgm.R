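#' Configuration of the synthetic CGM generator
#'
#' The generator emulates the structure of pediatric type-1 diabetes CGM
#' home-monitoring data: 5-minute sampling (288 samples/day), glucose
#' mostly in 3.5-15.5 mmol/L, slow circadian drift, post-meal excursions
#' and autocorrelated sensor noise. Each sample is
#' `baseline + circadian sinusoid + meal pulses + AR(1) noise`, clamped to
#' `clamp`. A meal starting at minute `t0` with magnitude `m` and rise time
#' `tau` contributes `m * (dt/tau) * exp(1 - dt/tau)` for `dt = t - t0 >= 0`
#' — a gamma-like pulse peaking at height `m` exactly `tau` minutes after
#' the meal. The AR(1) noise `e_t = rho * e_{t-1} + eps_t` with
#' `eps ~ N(0, sigma^2 (1 - rho^2))` has stationary standard deviation
#' `sigma`.
#'
#' @param days Number of simulated days (288 samples each).
#' @param baseline Baseline glucose, mmol/L (default 7.0).
#' @param circadian_amplitude Amplitude of the 24-h sinusoid, mmol/L
#'   (default 1.0).
#' @param meals Either a data.frame with columns `start_minute`,
#'   `magnitude` (mmol/L) and `tau` (minutes), or `NULL` (default) for 3
#'   random meals/day: start times in morning/midday/evening windows,
#'   magnitudes uniform in 2-6 mmol/L, rise times uniform in 30-60 min.
#' @param noise_rho AR(1) coefficient of the sensor noise (default 0.8).
#' @param noise_sigma Stationary noise standard deviation, mmol/L
#'   (default 0.15).
#' @param clamp Hard physiological bounds, mmol/L (default `c(2.2, 22.2)`).
#' @param sampling_period Minutes between samples (default 5).
#' @param seed RNG seed (Mersenne-Twister); identical seeds give
#'   bit-identical series.
#' @return A `sim_config` list.
#' @export
sim_config <- function(days = 2, baseline = 7.0, circadian_amplitude = 1.0,
                       meals = NULL, noise_rho = 0.8, noise_sigma = 0.15,
                       clamp = c(2.2, 22.2), sampling_period = 5, seed = 1) {
  stopifnot(days >= 1, noise_rho >= 0, noise_rho < 1, noise_sigma >= 0,
            length(clamp) == 2, clamp[1] < clamp[2], sampling_period > 0)
  structure(list(days = as.integer(days), baseline = baseline,
                 circadian_amplitude = circadian_amplitude, meals = meals,
                 noise_rho = noise_rho, noise_sigma = noise_sigma,
                 clamp = clamp, sampling_period = sampling_period,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic meal schedule: 3 meals/day drawn inside breakfast, lunch
# and dinner windows. Runs inside the generator's seeded RNG scope.
random_meals <- function(days) {
  windows <- list(c(6, 9), c(11.5, 14), c(17.5, 20)) # hours of day
  rows <- lapply(seq_len(days) - 1, function(d) {
    data.frame(
      start_minute = vapply(windows, function(w)
        d * 1440 + 60 * stats::runif(1, w[1], w[2]), numeric(1)),
      magnitude = stats::runif(3, 2, 6),
      tau = stats::runif(3, 30, 60))
  })
  do.call(rbind, rows)
}

#' Generate a seeded synthetic CGM profile
#'
#' @param cfg A [sim_config()].
#' @return A [glucose_series()] of `days * 288` samples at 5-min spacing
#'   (for the default period).
#' @examples
#' s <- generate_profile(sim_config(days = 1, seed = 42))
#' range(s$values)
#' @export
generate_profile <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- as.integer(cfg$days * round(1440 / cfg$sampling_period))
  t_min <- (seq_len(n) - 1) * cfg$sampling_period
  with_seed(cfg$seed, {
    meals <- if (is.null(cfg$meals)) random_meals(cfg$days) else cfg$meals
    signal <- cfg$baseline +
      cfg$circadian_amplitude * sin(2 * pi * t_min / 1440)
    for (i in seq_len(nrow(meals))) {
      dt <- t_min - meals$start_minute[i]
      on <- dt >= 0
      signal[on] <- signal[on] + meals$magnitude[i] *
        (dt[on] / meals$tau[i]) * exp(1 - dt[on] / meals$tau[i])
    }
    noise <- numeric(n)
    if (cfg$noise_sigma > 0) {
      eps <- stats::rnorm(n, 0,
                          cfg$noise_sigma * sqrt(1 - cfg$noise_rho^2))
      noise[1] <- stats::rnorm(1, 0, cfg$noise_sigma)
      for (i in seq_len(n)[-1])
        noise[i] <- cfg$noise_rho * noise[i - 1] + eps[i]
    }
    values <- pmin(pmax(signal + noise, cfg$clamp[1]), cfg$clamp[2])
    glucose_series(t_min, values, sampling_period = cfg$sampling_period,
                   subject_id = sprintf("sim-seed%d", cfg$seed))
  })
}

#' Punch measurement gaps into a series
#'
#' Removes the stated sample runs, returning raw `times`/`values` arrays
#' with holes — the shape real sensor dropouts leave, for exercising
#' [segment_by_gaps()]. Remaining samples are untouched.
#'
#' @param series A [glucose_series()].
#' @param gap_starts 1-based indices of the first removed sample of each
#'   gap.
#' @param gap_lengths Number of consecutive samples removed per gap; gaps
#'   must not overlap.
#' @return `list(times, values)` raw arrays.
#' @export
inject_gaps <- function(series, gap_starts, gap_lengths) {
  validate_glucose_series(series)
  stopifnot(length(gap_starts) == length(gap_lengths),
            all(gap_lengths >= 1))
  n <- length(series$values)
  drop_idx <- integer(0)
  for (g in seq_along(gap_starts)) {
    idx <- gap_starts[g]:(gap_starts[g] + gap_lengths[g] - 1)
    if (any(idx < 1 | idx > n)) stop("gap ", g, " extends outside the series")
    if (any(idx %in% drop_idx)) stop("gaps overlap")
    drop_idx <- c(drop_idx, idx)
  }
  keep <- setdiff(seq_len(n), drop_idx)
  list(times = series$times[keep], values = series$values[keep])
}
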