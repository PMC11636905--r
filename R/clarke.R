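#' Clarke error-grid zone classification
#'
#' Maps each (reference, predicted) glucose pair, in mg/dl, into the five
#' clinical accuracy zones of the Clarke error grid: A (clinically
#' accurate), B (benign deviation), C (overcorrection), D (dangerous
#' failure to detect hypo-/hyperglycemia), E (confusion of hypoglycemia
#' and hyperglycemia treatment). The boundary rules are the standard
#' published set, evaluated in precedence order A, E, C, D, else B, so
#' boundary ties resolve deterministically to the earlier zone:
#'
#' * A: `R <= 70 & P <= 70`, or `0.8 R <= P <= 1.2 R`
#' * E: `R >= 180 & P <= 70`, or `R <= 70 & P >= 180`
#' * C: `70 <= R <= 290 & P >= R + 110`, or
#'      `130 <= R <= 180 & P <= (7/5) R - 182`
#' * D: `R >= 240 & 70 <= P <= 180`, or `R <= 175/3 & 70 <= P <= 180`, or
#'      `175/3 <= R <= 70 & P >= (6/5) R`
#' * B: everything else
#'
#' @param ref Reference (measured) glucose in mg/dl, non-negative.
#' @param pred Predicted glucose in mg/dl, non-negative; recycled against
#'   `ref`.
#' @return Factor of zone labels `A`-`E`, one per pair.
#' @examples
#' clarke_zone(100, 100)  # A
#' clarke_zone(200, 60)   # E
#' @export
clarke_zone <- function(ref, pred) {
  n <- max(length(ref), length(pred))
  R <- rep_len(as.numeric(ref), n); P <- rep_len(as.numeric(pred), n)
  if (!all(is.finite(R)) || !all(is.finite(P)) || any(R < 0) || any(P < 0))
    stop("reference and predicted glucose must be finite and >= 0 mg/dl")
  z <- rep("B", n)
  isA <- (R <= 70 & P <= 70) | (P >= 0.8 * R & P <= 1.2 * R)
  isE <- (R >= 180 & P <= 70) | (R <= 70 & P >= 180)
  isC <- (R >= 70 & R <= 290 & P >= R + 110) |
    (R >= 130 & R <= 180 & P <= (7 / 5) * R - 182)
  isD <- (R >= 240 & P >= 70 & P <= 180) |
    (R <= 175 / 3 & P >= 70 & P <= 180) |
    (R >= 175 / 3 & R <= 70 & P >= (6 / 5) * R)
  z[isD] <- "D"; z[isC] <- "C"; z[isE] <- "E"; z[isA] <- "A"
  factor(z, levels = c("A", "B", "C", "D", "E"))
}

#' Per-zone percentages of prediction points
#'
#' Converts a [prediction_result()] (mmol/L) to mg/dl, classifies every
#' pair with [clarke_zone()] and reports the percentage of points per zone.
#'
#' @param r A [prediction_result()].
#' @return A `zone_summary`: list with `percent` (named A-E, summing to
#'   100), `counts` and `n_points`.
#' @export
zone_summary <- function(r) {
  stopifnot(inherits(r, "prediction_result"))
  z <- clarke_zone(mmol_to_mgdl(r$measured), mmol_to_mgdl(r$predicted))
  counts <- table(z)
  structure(list(percent = 100 * as.numeric(counts) / length(z),
                 counts = as.integer(counts),
                 n_points = length(z)),
            class = "zone_summary")
}

#' @export
print.zone_summary <- function(x, ...) {
  cat(sprintf("<zone_summary> n = %d | A %.2f%%  B %.2f%%  C %.2f%%  D %.2f%%  E %.2f%%\n",
              x$n_points, x$percent[1], x$percent[2], x$percent[3],
              x$percent[4], x$percent[5]))
  invisible(x)
}

#' Write zone summaries across horizons to CSV
#'
#' One row per horizon in zone order A-E, matching the layout of a
#' PH-sweep Clarke grid table.
#'
#' @param summaries Named list of `zone_summary` objects; names are the
#'   horizons in minutes.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_zone_csv <- function(summaries, path) {
  tab <- data.frame(
    ph_min = as.numeric(names(summaries)),
    t(vapply(summaries, function(s) s$percent, numeric(5))))
  names(tab)[2:6] <- c("percent_A", "percent_B", "percent_C",
                       "percent_D", "percent_E")
  tab <- tab[order(tab$ph_min), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
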