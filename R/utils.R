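# Internal helpers shared across modules.

# Conversion between the two circulating glucose units. The molar-mass
# convention 18.0182 mg/dl per mmol/L is frozen package-wide; 18.0 and 18.016
# also circulate in the literature, so the constant is kept in one place.
MGDL_PER_MMOL <- 18.0182

#' Convert glucose concentrations between mmol/L and mg/dl
#'
#' The package works internally in mmol/L; Clarke error-grid boundaries are
#' defined in mg/dl. The conversion factor is 18.0182 mg/dl per mmol/L.
#'
#' @param v Numeric vector of concentrations.
#' @return Numeric vector in the other unit.
#' @examples
#' mmol_to_mgdl(5.55)   # ~ 100 mg/dl
#' mgdl_to_mmol(mmol_to_mgdl(7.2)) # 7.2
#' @export
mmol_to_mgdl <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  v * MGDL_PER_MMOL
}

#' @rdname mmol_to_mgdl
#' @export
mgdl_to_mmol <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  v / MGDL_PER_MMOL
}

#' Number of recursive prediction steps for a horizon
#'
#' A prediction horizon of `ph_minutes` on a series sampled every
#' `sampling_period` minutes corresponds to `ph_minutes / sampling_period`
#' recursive one-step predictions; the horizon must be an exact multiple of
#' the sampling period.
#'
#' @param ph_minutes Prediction horizon in minutes.
#' @param sampling_period Sampling period in minutes (default 5).
#' @return Integer count of recursive steps.
#' @examples
#' horizon_steps(100, 5)  # 20
#' @export
horizon_steps <- function(ph_minutes, sampling_period = 5) {
  stopifnot(is.numeric(ph_minutes), ph_minutes > 0, sampling_period > 0)
  k <- ph_minutes / sampling_period
  if (abs(k - round(k)) > 1e-9) {
    stop("prediction horizon ", ph_minutes,
         " min is not a multiple of the sampling period (",
         sampling_period, " min)")
  }
  as.integer(round(k))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded internals never perturb user-level randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
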