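#' Wear-detection parameters
#'
#' The on-device temperature rises towards skin temperature while the sensor
#' is worn and relaxes to ambient when taken off.  Wear is detected
#' event-style from the smoothed temperature: a sample is "worn" when the
#' smoothed temperature exceeds `temp_threshold` or when a positive slope of
#' at least `slope_threshold` degC/min is sustained for `slope_sustain_s`
#' seconds (the warm-up after donning).  Segments shorter than
#' `min_segment_s` are absorbed into their surroundings.
#'
#' @param smooth_window_s centred moving-average window in s (default 5 min).
#' @param temp_threshold worn/ambient temperature threshold in degC.
#' @param slope_threshold sustained warming slope in degC/min.
#' @param slope_sustain_s minimum duration of the warming slope in s.
#' @param min_segment_s minimum worn / non-worn segment duration in s.
#' @return A list of class `fw_wear_params`.
#' @export
wear_params <- function(smooth_window_s = 300, temp_threshold = 27,
                        slope_threshold = 0.1, slope_sustain_s = 120,
                        min_segment_s = 600) {
  stopifnot(smooth_window_s > 0, slope_sustain_s >= 0, min_segment_s >= 0)
  structure(list(smooth_window_s = smooth_window_s,
                 temp_threshold = temp_threshold,
                 slope_threshold = slope_threshold,
                 slope_sustain_s = slope_sustain_s,
                 min_segment_s = min_segment_s), class = "fw_wear_params")
}

#' Detect sensor wear from the temperature channel
#'
#' @param temperature numeric temperature series in degC (NAs tolerated; an
#'   all-missing series falls back to "worn throughout" with a warning).
#' @param temp_rate sampling rate of the temperature series in samples/s.
#' @param params see [wear_params()].
#' @param duration recording duration in s; the returned intervals partition
#'   `[0, duration]`.  Defaults to the span of the temperature series.
#' @return A data.frame with columns `start`, `end` (s from recording start)
#'   and logical `worn`; intervals are sorted, non-overlapping and cover the
#'   recording exactly.
#' @export
detect_wear <- function(temperature, temp_rate, params = wear_params(),
                        duration = NULL) {
  n <- length(temperature)
  if (is.null(duration)) duration <- n / temp_rate
  if (n == 0L || all(is.na(temperature))) {
    warning("temperature channel missing or all NA: assuming worn throughout")
    return(data.frame(start = 0, end = duration, worn = TRUE))
  }
  temperature <- approx(seq_len(n), temperature, xout = seq_len(n),
                        rule = 2)$y # fill interior/edge NAs
  sm <- moving_average(temperature, round(params$smooth_window_s * temp_rate))
  worn <- sm >= params$temp_threshold
  # sustained positive slope marks the warm-up after donning as worn
  if (n >= 3L && params$slope_threshold > 0) {
    slope <- c(0, diff(sm)) * temp_rate * 60 # degC per minute
    pos <- slope >= params$slope_threshold
    need <- max(1L, round(params$slope_sustain_s * temp_rate))
    r <- rle(pos)
    keep <- r$values & r$lengths >= need
    if (any(keep)) {
      idx <- cumsum(r$lengths)
      for (j in which(keep))
        worn[(idx[j] - r$lengths[j] + 1L):idx[j]] <- TRUE
    }
  }
  worn <- merge_short_runs(worn, max(1L, round(params$min_segment_s * temp_rate)))
  r <- rle(worn)
  ends <- cumsum(r$lengths) / temp_rate
  ends[length(ends)] <- duration
  starts <- c(0, head(ends, -1L))
  data.frame(start = starts, end = ends, worn = r$values)
}

# Absorb runs shorter than min_len samples into their surroundings,
# shortest first, so brief temperature excursions do not fragment wear.
merge_short_runs <- function(x, min_len) {
  repeat {
    r <- rle(x)
    if (length(r$lengths) <= 1L) return(x)
    short <- which(r$lengths < min_len)
    if (!length(short)) return(x)
    j <- short[which.min(r$lengths[short])]
    idx <- cumsum(r$lengths)
    from <- idx[j] - r$lengths[j] + 1L
    x[from:idx[j]] <- !r$values[j]
  }
}

#' Per-day wear summary and valid-day classification
#'
#' Splits worn time across calendar days (local midnight-to-midnight from
#' `start_time`) and flags days with at least `min_wear_hours` of wear as
#' valid.  For compressed synthetic days (`day_seconds < 86400`) the same
#' rule is applied proportionally: a day is valid when the worn fraction is
#' at least `min_wear_hours / 24`, and `wear_hours` is reported on the
#' equivalent 24 h clock.
#'
#' @param intervals wear intervals from [detect_wear()].
#' @param start_time recording start (`POSIXct`).
#' @param duration recording duration in s.
#' @param day_seconds length of one day window in s (86400 for real days).
#' @param min_wear_hours valid-day wear threshold in h (default 18).
#' @return data.frame with `date`, `day_index`, `wear_hours`, `is_valid`.
#' @export
day_wear_summary <- function(intervals, start_time, duration,
                             day_seconds = 86400, min_wear_hours = 18) {
  stopifnot(day_seconds > 0)
  if (day_seconds == 86400) {
    midnight <- as.POSIXct(format(start_time, "%Y-%m-%d"), tz = "UTC")
    off0 <- -as.numeric(difftime(start_time, midnight, units = "secs"))
  } else {
    off0 <- 0 # compressed days anchor at the recording start
  }
  nday <- ceiling((duration - off0) / day_seconds)
  worn <- intervals[intervals$worn, , drop = FALSE]
  out <- lapply(seq_len(nday), function(k) {
    lo <- off0 + (k - 1) * day_seconds
    hi <- lo + day_seconds
    ov <- pmax(0, pmin(worn$end, hi) - pmax(worn$start, lo))
    wh <- sum(ov) / day_seconds * 24
    data.frame(date = as.Date(start_time) + (k - 1L),
               day_index = k, wear_hours = wh,
               is_valid = wh >= min_wear_hours)
  })
  do.call(rbind, out)
}
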