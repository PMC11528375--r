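#' Pairwise mismatch percentage
#'
#' Relative disagreement between two measurements of the same quantity,
#' normalized by their mean: `|m1 - m2| / ((m1 + m2) / 2) * 100`. Symmetric,
#' scale-invariant and zero iff the values agree.
#'
#' @param m1,m2 positive values (scalars or vectors, recycled).
#' @return Mismatch in percent.
#' @export
mismatch_percent <- function(m1, m2) {
  if (any(m1 <= 0) || any(m2 <= 0)) stop("mismatch needs positive inputs")
  abs(m1 - m2) / ((m1 + m2) / 2) * 100
}

#' Aligned rater-pair table
#'
#' One row per hippocampus with both raters' values of a single descriptor.
#'
#' @param patient_id,side identifying keys (equal length).
#' @param rater1,rater2 the two raters' measurements (positive, no missing
#'   values: pairing must be complete).
#' @param descriptor descriptor name (e.g. `"volume_cm3"`).
#' @param units unit string for reports.
#' @return A `data.frame` of class `rater_pair_table`.
#' @export
rater_pair_table <- function(patient_id, side, rater1, rater2,
                             descriptor = "volume_cm3", units = "cm^3") {
  if (anyNA(rater1) || anyNA(rater2))
    stop("pairing incomplete: missing measurements")
  if (any(rater1 <= 0) || any(rater2 <= 0))
    stop("size descriptors must be positive")
  out <- data.frame(patient_id = patient_id, side = side,
                    rater1 = rater1, rater2 = rater2)
  attr(out, "descriptor") <- descriptor
  attr(out, "units") <- units
  class(out) <- c("rater_pair_table", "data.frame")
  out
}

#' Tolerance match rate between raters
#'
#' A pair matches when its [mismatch_percent()] is at most `tolerance`.
#' The percentage is rounded to the nearest integer for reporting
#' (25 matched of 126 reads as 20%).
#'
#' @param pairs a [rater_pair_table()].
#' @param tolerance match tolerance in percent (default 3).
#' @return List with `matched`, `total`, `percent`.
#' @export
match_rate <- function(pairs, tolerance = 3) {
  if (nrow(pairs) == 0) stop("empty pair table")
  mm <- mismatch_percent(pairs$rater1, pairs$rater2)
  matched <- sum(mm <= tolerance)
  list(matched = matched, total = nrow(pairs),
       percent = round(100 * matched / nrow(pairs)))
}

#' Iterative segmentation tuning protocol
#'
#' Book-keeping for the agreement tuning loop used with paired manual
#' segmentations: in each round the per-pair mismatch is measured, pairs
#' above the threshold are flagged, and a revision callback supplies
#' updated values for the flagged pairs (in the real protocol this is the
#' raters re-examining their traces; in tests, a simulated revision). The
#' loop stops when the summary (mean) mismatch drops to the threshold or
#' the round limit is hit. Round 0 is the unrevised baseline.
#'
#' @param pairs a [rater_pair_table()].
#' @param threshold mismatch threshold in percent (default 3).
#' @param revise callback `function(pairs, flagged_idx)` returning the
#'   revised pair table.
#' @param max_rounds revision limit.
#' @return List of class `tuning_report`: `rounds` (one record per round
#'   with `round`, `mean_mismatch`, `flagged` keys and per-pair mismatch),
#'   `converged`, `final_match_rate` (percent at the same threshold),
#'   `pairs` (final table).
#' @export
tuning_loop <- function(pairs, threshold = 3, revise, max_rounds = 10) {
  rounds <- list()
  converged <- FALSE
  for (round in 0:max_rounds) {
    mm <- mismatch_percent(pairs$rater1, pairs$rater2)
    flagged <- which(mm > threshold)
    rounds[[length(rounds) + 1]] <- list(
      round = round, mismatch = mm, mean_mismatch = mean(mm),
      flagged = pairs$patient_id[flagged], n_flagged = length(flagged))
    if (mean(mm) <= threshold) { converged <- TRUE; break }
    if (round == max_rounds) break
    pairs <- revise(pairs, flagged)
  }
  structure(list(rounds = rounds, converged = converged,
                 final_match_rate = match_rate(pairs, threshold)$percent,
                 pairs = pairs),
            class = "tuning_report")
}

#' Inter-rater calibration regression
#'
#' Ordinary least squares of the rater-2 values on rater-1, with the
#' percentage error `E = 100 * b / xbar`, where `b` is the intercept and
#' `xbar` the mean of all pooled measurements from both raters.
#'
#' @param pairs a [rater_pair_table()] with >= 3 rows.
#' @return List of class `rater_regression`: `slope`, `intercept`,
#'   `r_squared`, `percent_error`, `pooled_mean`.
#' @export
rater_regression <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (stats::var(pairs$rater1) == 0) stop("zero variance in rater-1 values")
  fit <- stats::lm(rater2 ~ rater1, data = pairs)
  b <- unname(stats::coef(fit)[1])
  xbar <- mean(c(pairs$rater1, pairs$rater2))
  structure(list(slope = unname(stats::coef(fit)[2]), intercept = b,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 percent_error = 100 * b / xbar,
                 pooled_mean = xbar),
            class = "rater_regression")
}

#' @export
print.rater_regression <- function(x, ...) {
  cat(sprintf("y = %.3f x + %.3f   R^2 = %.3f   E = %.2f%% (pooled mean %.3f)\n",
              x$slope, x$intercept, x$r_squared, x$percent_error, x$pooled_mean))
  invisible(x)
}
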