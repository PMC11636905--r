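# Batch closed-loop recursion: every row of `seedmat` is an independent tap
# buffer; all buffers are advanced together, one matrix op per step.
recursive_matrix <- function(model, seedmat, n_steps) {
  stopifnot(model$mode == "closed_loop",
            ncol(seedmat) == model$config$n_taps)
  sc <- model$scaler
  buf <- apply_scaler(sc, seedmat)
  out <- matrix(NA_real_, nrow(seedmat), n_steps)
  for (k in seq_len(n_steps)) {
    p <- narx_forward_scaled(model$weights, buf)$yhat
    out[, k] <- p
    buf <- cbind(buf[, -1, drop = FALSE], p)
  }
  invert_scaler(sc, out)
}

#' Sliding multi-horizon evaluation of a glucose predictor
#'
#' For each horizon `PH = k * sampling_period`: slide over the test series
#' with the given stride, feed the `n_taps` true values before each
#' position into the closed-loop network, recursively predict `k` steps,
#' and pair the step-`k` prediction with the true value `k` samples ahead.
#' The series is evaluated as given — supply the smoothed series for the
#' standard protocol, or the raw series for raw-measurement evaluation.
#'
#' @param model A closed-loop `narx_model`.
#' @param test_series A [glucose_series()] (typically smoothed).
#' @param horizons Prediction horizons in minutes (default
#'   `c(15, 30, 45, 60, 90, 100)`); each must be a multiple of the
#'   sampling period and at most `n_taps` steps.
#' @param stride Sliding step over the test series, in samples (default 1).
#' @return List with `results` (one [prediction_result()] per horizon),
#'   `metrics` (the [metric_table()]) and `zones` (named list of
#'   [zone_summary()] per horizon).
#' @export
evaluate_horizons <- function(model, test_series,
                              horizons = c(15, 30, 45, 60, 90, 100),
                              stride = 1) {
  stopifnot(inherits(model, "narx_model"))
  if (model$mode != "closed_loop")
    stop("model must be closed-loop; call close_loop() first")
  validate_glucose_series(test_series)
  v <- test_series$values
  nt <- model$config$n_taps
  results <- lapply(horizons, function(ph) {
    k <- horizon_steps(ph, test_series$sampling_period)
    if (k > nt) stop("horizon ", ph, " min exceeds the ", nt, "-step cap")
    last <- length(v) - nt - k + 1
    if (last < 2)
      stop("test series too short for horizon ", ph, " min")
    pos <- seq(1, last, by = stride)
    seedmat <- t(vapply(pos, function(p) v[p:(p + nt - 1)], numeric(nt)))
    preds <- recursive_matrix(model, seedmat, k)
    prediction_result(measured = v[pos + nt + k - 1],
                      predicted = preds[, k], horizon_minutes = ph)
  })
  zones <- lapply(results, zone_summary)
  names(zones) <- as.character(horizons)
  list(results = results, metrics = metric_table(results), zones = zones)
}

#' Persistence (last-value) baseline over the same sliding protocol
#'
#' The naive forecaster that repeats the newest tap value at every horizon
#' — the reference any learned predictor must beat.
#'
#' @param test_series A [glucose_series()].
#' @param horizons Horizons in minutes.
#' @param n_taps Tap count matching the evaluated model (default 20), so
#'   the evaluated positions are identical.
#' @param stride Sliding step in samples.
#' @return Same structure as [evaluate_horizons()].
#' @export
persistence_baseline <- function(test_series,
                                 horizons = c(15, 30, 45, 60, 90, 100),
                                 n_taps = 20, stride = 1) {
  validate_glucose_series(test_series)
  v <- test_series$values
  results <- lapply(horizons, function(ph) {
    k <- horizon_steps(ph, test_series$sampling_period)
    last <- length(v) - n_taps - k + 1
    if (last < 2) stop("test series too short for horizon ", ph, " min")
    pos <- seq(1, last, by = stride)
    prediction_result(measured = v[pos + n_taps + k - 1],
                      predicted = v[pos + n_taps - 1], horizon_minutes = ph)
  })
  zones <- lapply(results, zone_summary)
  names(zones) <- as.character(horizons)
  list(results = results, metrics = metric_table(results), zones = zones)
}

#' End-to-end training pipeline from a raw CGM trace
#'
#' Segments the raw trace around measurement gaps, smooths each segment
#' with the span-11 moving average, assigns the first `n_test` samples (in
#' segment order) to the test set and the remainder to training, cuts
#' 20-in/20-out sliding windows within each training segment, trains the
#' network open-loop and closes the loop.
#'
#' @param times Raw timestamps in minutes.
#' @param values Raw glucose in mmol/L.
#' @param sampling_period Minutes between samples (default 5).
#' @param span Smoothing span (default 11).
#' @param max_gap Gap threshold in minutes (default `2 * sampling_period`).
#' @param n_test Leading samples reserved for testing (default 500).
#' @param config A [narx_config()].
#' @param tc A [train_config()].
#' @param stride Window stride (default 1).
#' @return List with `model` (closed-loop, trained), `report` (the
#'   training report), `test` (smoothed test [glucose_series()]) and
#'   `train_segments` (smoothed training segments).
#' @export
train_glucose_predictor <- function(times, values, sampling_period = 5,
                                    span = 11,
                                    max_gap = 2 * sampling_period,
                                    n_test = 500,
                                    config = narx_config(),
                                    tc = train_config(), stride = 1) {
  segs <- segment_by_gaps(times, values, sampling_period = sampling_period,
                          max_gap = max_gap,
                          min_length = config$n_taps * 2)
  if (length(segs) == 0) stop("no usable segments after gap exclusion")
  segs <- lapply(segs, smooth_series, span = span)
  total <- sum(vapply(segs, length, integer(1)))
  if (n_test >= total)
    stop("n_test (", n_test, ") >= available samples (", total, ")")

  test_parts <- list(); train_segs <- list(); remaining <- n_test
  for (seg in segs) {
    L <- length(seg)
    if (remaining >= L) {
      test_parts[[length(test_parts) + 1L]] <- seg
      remaining <- remaining - L
    } else if (remaining > 0) {
      sp <- split_first_n(seg, remaining)
      test_parts[[length(test_parts) + 1L]] <- sp$test
      train_segs[[length(train_segs) + 1L]] <- sp$train
      remaining <- 0
    } else {
      train_segs[[length(train_segs) + 1L]] <- seg
    }
  }
  if (remaining > 0) stop("not enough samples to fill the test set")
  if (length(train_segs) == 0) stop("no training segments left after split")

  windows <- do.call(c, lapply(train_segs, make_windows,
                               n_in = config$n_taps, n_out = config$n_taps,
                               stride = stride))
  if (length(windows) == 0)
    stop("training segments too short to cut any window")

  fit <- train_open_loop(narx_model(config), windows, tc)
  # Test set: the protocol evaluates within one uniform block; use the
  # first (typically only) test segment.
  list(model = close_loop(fit$model), report = fit$report,
       test = test_parts[[1]], test_parts = test_parts,
       train_segments = train_segs)
}

#' Scripted entry points: simulate, train, evaluate
#'
#' Thin wrappers used by the command-line interface
#' (`inst/cli/glynarx.R`): each runs one pipeline stage and writes its
#' outputs plus a `manifest.json` (configuration, seeds, package version)
#' sufficient to reproduce the run byte for byte.
#'
#' @param days,seed Simulation length (days) and RNG seed.
#' @param out Output file (`run_simulate`: CGM CSV; `run_train`: model
#'   JSON) or directory (`run_evaluate`).
#' @param ... Passed to [sim_config()] (`run_simulate`) or
#'   [train_glucose_predictor()] (`run_train`).
#' @return `run_simulate`: the generated [glucose_series()];
#'   `run_train`: the pipeline result list; `run_evaluate`: the
#'   [evaluate_horizons()] result list. All invisibly.
#' @export
run_simulate <- function(days = 2, seed = 1, out, ...) {
  s <- generate_profile(sim_config(days = days, seed = seed, ...))
  write_cgm_csv(s, out)
  write_manifest(paste0(out, ".manifest.json"),
                 list(command = "simulate", days = days, seed = seed))
  invisible(s)
}

#' @rdname run_simulate
#' @param input Path to a CGM CSV (package dialect, mmol/L).
#' @param n_test Leading samples reserved for testing.
#' @param tc Training settings, a [train_config()].
#' @export
run_train <- function(input, out, n_test = 500, seed = 1,
                      tc = train_config(seed = seed), ...) {
  s <- read_cgm_csv(input)
  res <- train_glucose_predictor(s$times, s$values,
                                 sampling_period = s$sampling_period,
                                 n_test = n_test,
                                 config = narx_config(seed = seed),
                                 tc = tc, ...)
  save_narx(res$model, out)
  write_manifest(paste0(out, ".manifest.json"),
                 list(command = "train", input = input, n_test = n_test,
                      seed = seed, report = res$report))
  invisible(res)
}

#' @rdname run_simulate
#' @param model_path Path to a saved model (from [save_narx()]).
#' @param horizons Horizons in minutes to evaluate.
#' @param span Smoothing span applied to the test series before
#'   evaluation (the standard protocol evaluates against smoothed
#'   measurements); set `NULL` to evaluate raw.
#' @export
run_evaluate <- function(model_path, input, out,
                         horizons = c(15, 30, 45, 60, 90, 100),
                         n_test = NULL, span = 11, seed = 1) {
  model <- load_narx(model_path)
  if (model$mode == "open_loop") model <- close_loop(model)
  s <- read_cgm_csv(input)
  if (!is.null(n_test)) s <- split_first_n(s, n_test)$test
  if (!is.null(span)) s <- smooth_series(s, span)
  ev <- evaluate_horizons(model, s, horizons = horizons)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_metric_csv(ev$metrics, file.path(out, "metrics.csv"))
  write_zone_csv(ev$zones, file.path(out, "zones.csv"))
  write_manifest(file.path(out, "manifest.json"),
                 list(command = "evaluate", model = model_path,
                      input = input, horizons = horizons,
                      n_test = n_test, span = span, seed = seed))
  invisible(ev)
}

write_manifest <- function(path, fields) {
  fields$package_version <- as.character(utils::packageVersion("glynarx"))
  writeLines(jsonlite::toJSON(fields, auto_unbox = TRUE, pretty = TRUE,
                              digits = I(17)), path)
  invisible(path)
}
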