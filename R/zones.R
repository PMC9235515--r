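#' Divergence-zone thresholds
#'
#' The default Markov-time boundaries of the divergence zones: daylight up to
#' 150 (sequence and structure alignments agree closely), twilight up to 250
#' (residue-level correspondences become unreliable), midnight up to 350
#' (sequence evidence of the relationship is largely gone), and beyond 350
#' the pair has diverged past the limit of inference of pairwise sequence
#' alignment. Each upper bound is inclusive.
#'
#' @param daylight_max,twilight_max,midnight_max strictly increasing
#'   Markov-time boundaries (defaults 150, 250, 350).
#' @return a named numeric vector of class `zone_thresholds`.
#' @export
zone_thresholds <- function(daylight_max = 150, twilight_max = 250,
                            midnight_max = 350) {
  th <- c(daylight_max = daylight_max, twilight_max = twilight_max,
          midnight_max = midnight_max)
  if (any(diff(th) <= 0) || any(th <= 0))
    stop("zone thresholds must be positive and strictly increasing")
  structure(th, class = "zone_thresholds")
}

#' Classify an inferred Markov time into a divergence zone
#'
#' @param time non-negative inferred Markov time(s) (vectorized).
#' @param thresholds a [zone_thresholds()] object.
#' @return factor with levels `daylight`, `twilight`, `midnight`, `beyond`;
#'   every non-negative time receives exactly one label.
#' @export
#' @examples
#' classify_zone(c(49, 307))
classify_zone <- function(time, thresholds = zone_thresholds()) {
  if (any(!is.finite(time)) || any(time < 0))
    stop("Markov time must be non-negative")
  lab <- ifelse(time <= thresholds[["daylight_max"]], "daylight",
         ifelse(time <= thresholds[["twilight_max"]], "twilight",
         ifelse(time <= thresholds[["midnight_max"]], "midnight", "beyond")))
  factor(lab, levels = c("daylight", "twilight", "midnight", "beyond"))
}

#' Compression-based relationship group of a pair
#'
#' Partitions pairs by their compression statistics: group1 when the optimal
#' alignment itself is statistically significant (`delta_optimal > 0`);
#' group2 when no single alignment compresses but the marginal over all
#' alignments does (`delta_optimal <= 0 < delta_marginal`); group3 when even
#' the marginal loses to the null (`delta_marginal <= 0`).
#'
#' @param delta_optimal,delta_marginal compression gains in bits (vectorized).
#' @return factor with levels `group1`, `group2`, `group3`.
#' @export
compression_group <- function(delta_optimal, delta_marginal) {
  if (any(!is.finite(delta_optimal)) || any(!is.finite(delta_marginal)))
    stop("delta statistics must be finite")
  lab <- ifelse(delta_optimal > 0, "group1",
         ifelse(delta_marginal > 0, "group2", "group3"))
  factor(lab, levels = c("group1", "group2", "group3"))
}

#' Quartile-versus-time survey summary
#'
#' Bins survey records by their integer inferred Markov time and tracks the
#' first, second and third quartiles of the normalized expected distance per
#' bin, plus the cumulative percentage of pairs up to each bin — the desk
#' scale analogue of the quartile-versus-time survey plots.
#'
#' @param records data frame with columns `time_marginal` and
#'   `expected_distance` (normalized).
#' @param time_range integer bin range (default `c(1, 500)`); records outside
#'   it are dropped.
#' @return data frame with columns `bin`, `n`, `q1`, `q2`, `q3`,
#'   `cumulative_pct` (one row per populated bin, ascending). Quartiles use
#'   linear interpolation (R's default type 7).
#' @export
quartile_summary <- function(records, time_range = c(1, 500)) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data frame")
  if (!all(c("time_marginal", "expected_distance") %in% names(records)))
    stop("records needs columns time_marginal and expected_distance")
  bin <- round(records$time_marginal)
  keep <- bin >= time_range[1] & bin <= time_range[2]
  bin <- bin[keep]
  x <- records$expected_distance[keep]
  if (!length(x)) stop("no records fall inside the time range")
  bins <- sort(unique(bin))
  qs <- t(vapply(bins, function(b)
    quantile(x[bin == b], c(0.25, 0.5, 0.75), names = FALSE, type = 7),
    numeric(3)))
  counts <- vapply(bins, function(b) sum(bin == b), numeric(1))
  data.frame(bin = bins, n = counts, q1 = qs[, 1], q2 = qs[, 2], q3 = qs[, 3],
             cumulative_pct = 100 * cumsum(counts) / sum(counts))
}
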