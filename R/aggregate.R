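#' Mean daily step count over valid days
#'
#' Steps within all bouts on valid days are summed per day and averaged
#' across valid days (days without bouts contribute zero).  Returns `NA`
#' when no day is valid.
#'
#' @param bouts bout table (see [summarize_bout()]) with a `day_index` and
#'   `n_steps` column.
#' @param days day records from [day_wear_summary()].
#' @return steps/day, or `NA_real_` when there is no valid day.
#' @export
mean_daily_steps <- function(bouts, days) {
  valid <- days$day_index[days$is_valid]
  if (!length(valid)) return(NA_real_)
  per_day <- vapply(valid, function(d)
    sum(bouts$n_steps[bouts$day_index == d]), numeric(1))
  mean(per_day)
}

#' 95th percentile with linear interpolation
#'
#' Linear interpolation between order statistics at position
#' `1 + p * (n - 1)` (the common statistical default).
#'
#' @param values numeric sample.
#' @param p probability (default 0.95).
#' @return the percentile, or `NA_real_` for an empty sample.
#' @export
percentile95 <- function(values, p = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (!n) return(NA_real_)
  s <- sort(values)
  pos <- 1 + p * (n - 1)
  lo <- floor(pos)
  hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[hi] - s[lo])
}

#' Histogram mode of a continuous variable
#'
#' The mode is the midpoint of the most populated histogram bin, with bins
#' of width `bin_width` anchored at zero and ties broken towards the lower
#' bin.  Used to represent habitual cadence / speed.
#'
#' @param values numeric sample (non-negative in intended use).
#' @param bin_width bin width in the variable's units.
#' @return bin midpoint, or `NA_real_` for an empty sample.
#' @export
mode_estimate <- function(values, bin_width) {
  stopifnot(bin_width > 0)
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  bins <- floor(values / bin_width)
  tab <- table(bins)
  best <- as.numeric(names(tab)[which.max(tab)]) # first max = lowest bin
  (best + 0.5) * bin_width
}

#' Bout duration-category distribution and time budget
#'
#' Bouts are classified into the four duration categories <=10 s,
#' >10-30 s, >30-60 s and >60 s (boundaries belong to the shorter
#' category).  Returns the proportion of bouts and the accumulated minutes
#' per category.
#'
#' @param bouts bout table with a `duration` column (seconds).
#' @return list with `proportions` (4 fractions summing to 1, all `NA` when
#'   there are no bouts) and `minutes` (4 accumulated durations in min).
#' @export
duration_category_summary <- function(bouts) {
  labs <- c("le10s", "gt10_30s", "gt30_60s", "gt60s")
  d <- bouts$duration
  # left-open intervals put exact boundaries (10, 30, 60 s) in the shorter
  # category, honouring "<=10 s", ">10-30 s", ...
  cat <- findInterval(d, c(10, 30, 60), left.open = TRUE) + 1L
  minutes <- vapply(1:4, function(k) sum(d[cat == k]) / 60, numeric(1))
  props <- if (length(d)) vapply(1:4, function(k) mean(cat == k), numeric(1))
           else rep(NA_real_, 4)
  list(proportions = setNames(props, labs),
       minutes = setNames(minutes, labs))
}

#' Maximum walking-bout distance
#'
#' @param bouts bout table with a `distance` column.
#' @return longest single-bout distance in m, `NA_real_` without bouts.
#' @export
max_bout_distance <- function(bouts) {
  if (!nrow(bouts)) return(NA_real_)
  max(bouts$distance)
}

#' Aggregation configuration
#'
#' @param cadence_bin habitual-cadence histogram bin width in steps/min.
#' @param speed_bin habitual-speed histogram bin width in m/s.
#' @param weekly_valid_days_only if `TRUE`, weekly (pooled-bout) metrics use
#'   only bouts on valid days; the default pools all bouts and restricts
#'   only the daily step count to valid days.
#' @return list of class `fw_agg_config`.
#' @export
agg_config <- function(cadence_bin = 2, speed_bin = 0.05,
                       weekly_valid_days_only = FALSE) {
  stopifnot(cadence_bin > 0, speed_bin > 0)
  structure(list(cadence_bin = cadence_bin, speed_bin = speed_bin,
                 weekly_valid_days_only = weekly_valid_days_only),
            class = "fw_agg_config")
}

#' Per-subject gait outcome metrics
#'
#' Combines daily aggregation (mean daily steps across valid days) with
#' weekly aggregation (statistics over all pooled bouts): habitual (mode)
#' and fast (95th percentile) cadence and speed, maximum bout distance, and
#' the bout-duration category distribution and time budget.
#'
#' @param bouts bout table (zero rows allowed).
#' @param days day records from [day_wear_summary()].
#' @param config see [agg_config()].
#' @return One-row data.frame with columns `daily_steps`, `fast_cadence`,
#'   `habitual_cadence`, `fast_speed`, `habitual_speed`, `max_distance`,
#'   `prop_*` and `min_*` for the four duration categories, `n_valid_days`,
#'   `n_bouts`.
#' @export
build_subject_summary <- function(bouts, days, config = agg_config()) {
  weekly <- if (config$weekly_valid_days_only)
    bouts[bouts$day_index %in% days$day_index[days$is_valid], , drop = FALSE]
  else bouts
  cats <- duration_category_summary(weekly)
  data.frame(
    daily_steps = mean_daily_steps(bouts, days),
    fast_cadence = percentile95(weekly$cadence),
    habitual_cadence = mode_estimate(weekly$cadence, config$cadence_bin),
    fast_speed = percentile95(weekly$speed),
    habitual_speed = mode_estimate(weekly$speed, config$speed_bin),
    max_distance = max_bout_distance(weekly),
    prop_le10s = cats$proportions[[1L]], prop_gt10_30s = cats$proportions[[2L]],
    prop_gt30_60s = cats$proportions[[3L]], prop_gt60s = cats$proportions[[4L]],
    min_le10s = cats$minutes[[1L]], min_gt10_30s = cats$minutes[[2L]],
    min_gt30_60s = cats$minutes[[3L]], min_gt60s = cats$minutes[[4L]],
    n_valid_days = sum(days$is_valid), n_bouts = nrow(weekly))
}
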