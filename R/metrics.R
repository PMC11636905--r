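#' Pair measured and predicted glucose at a stated horizon
#'
#' The common currency for evaluation: aligned measured/predicted glucose
#' pairs at one prediction horizon, feeding [rmse()], [fit_percent()],
#' [npe_percent()] and [zone_summary()].
#'
#' @param measured Measured glucose values (mmol/L).
#' @param predicted Predicted glucose values (mmol/L), same length.
#' @param horizon_minutes Prediction horizon in minutes.
#' @return A `prediction_result`.
#' @export
prediction_result <- function(measured, predicted, horizon_minutes) {
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  if (length(measured) != length(predicted))
    stop("measured and predicted differ in length")
  if (length(measured) < 2) stop("need at least 2 prediction pairs")
  if (!all(is.finite(measured)) || !all(is.finite(predicted)))
    stop("non-finite values in prediction result")
  structure(list(measured = measured, predicted = predicted,
                 horizon_minutes = horizon_minutes),
            class = "prediction_result")
}

#' Root mean squared prediction error
#'
#' `sqrt(mean((G - Ghat)^2))` in mmol/L; zero iff the prediction is exact.
#'
#' @param r A [prediction_result()].
#' @return RMSE in mmol/L.
#' @export
rmse <- function(r) {
  stopifnot(inherits(r, "prediction_result"))
  sqrt(mean((r$measured - r$predicted)^2))
}

#' FIT: percentage of data variation explained by the prediction
#'
#' `(1 - ||G - Ghat|| / ||G - mean(G)||) * 100` with the Euclidean norm.
#' 100% is a perfect prediction; 0% is no better than predicting the mean
#' of the measurements; negative values (worse than the mean predictor)
#' are reported as-is, never clipped.
#'
#' @param r A [prediction_result()]; the measured sequence must not be
#'   constant.
#' @return FIT in percent (at most 100).
#' @export
fit_percent <- function(r) {
  stopifnot(inherits(r, "prediction_result"))
  dev <- r$measured - mean(r$measured)
  denom <- sqrt(sum(dev^2))
  if (denom == 0)
    stop("FIT is undefined for a constant measured sequence")
  (1 - sqrt(sum((r$measured - r$predicted)^2)) / denom) * 100
}

#' NPE: residual norm as a percentage of the signal norm
#'
#' `sqrt(sum((G - Ghat)^2) / sum(G^2)) * 100`; zero iff the prediction is
#' exact, 100 when the residual is as large as the signal itself.
#'
#' @param r A [prediction_result()]; measured values must not all be zero.
#' @return NPE in percent.
#' @export
npe_percent <- function(r) {
  stopifnot(inherits(r, "prediction_result"))
  denom <- sum(r$measured^2)
  if (denom == 0) stop("NPE is undefined when all measured values are zero")
  sqrt(sum((r$measured - r$predicted)^2) / denom) * 100
}

#' Tabulate the three evaluation statistics across horizons
#'
#' One row per prediction horizon with NPE (%), RMSE (mmol/L) and FIT (%),
#' sorted by horizon — the layout of a standard PH-sweep evaluation table.
#'
#' @param results List of [prediction_result()] objects, one per horizon.
#' @return A `data.frame` with columns `ph_min`, `npe_percent`,
#'   `rmse_mmol_per_l`, `fit_percent`.
#' @export
metric_table <- function(results) {
  stopifnot(length(results) >= 1)
  ph <- vapply(results, function(r) r$horizon_minutes, numeric(1))
  if (anyDuplicated(ph)) stop("duplicate prediction horizons in results")
  tab <- data.frame(
    ph_min = ph,
    npe_percent = vapply(results, npe_percent, numeric(1)),
    rmse_mmol_per_l = vapply(results, rmse, numeric(1)),
    fit_percent = vapply(results, fit_percent, numeric(1)))
  tab[order(tab$ph_min), , drop = FALSE]
}

#' Write a metric table to CSV
#'
#' @param tab Output of [metric_table()].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_metric_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
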