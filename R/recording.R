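#' Construct a recording object
#'
#' A recording holds a multi-day triaxial acceleration series from a
#' lower-back sensor (vertical, antero-posterior, medio-lateral, in g) plus
#' an optional on-device temperature channel used for wear detection.
#'
#' @param acc_v,acc_ap,acc_ml numeric acceleration series in g, equal length.
#' @param rate sampling rate in samples/s (must be > 0).
#' @param subject_id subject identifier.
#' @param start_time `POSIXct` start of the recording (UTC assumed).
#' @param temperature optional numeric temperature series in degrees C.
#' @param temp_rate sampling rate of the temperature channel.
#' @return An object of class `fw_recording`.
#' @export
new_recording <- function(acc_v, acc_ap, acc_ml, rate,
                          subject_id = "S1",
                          start_time = as.POSIXct("2023-05-01 00:00:00",
                                                  tz = "UTC"),
                          temperature = NULL, temp_rate = 1) {
  stopifnot(rate > 0, length(acc_v) == length(acc_ap),
            length(acc_v) == length(acc_ml))
  if (anyNA(acc_v) || anyNA(acc_ap) || anyNA(acc_ml))
    stop("acceleration series must not contain missing values")
  structure(list(subject_id = as.character(subject_id),
                 rate = as.numeric(rate),
                 start_time = as.POSIXct(start_time, tz = "UTC"),
                 acc_v = as.numeric(acc_v),
                 acc_ap = as.numeric(acc_ap),
                 acc_ml = as.numeric(acc_ml),
                 temperature = if (is.null(temperature)) NULL
                               else as.numeric(temperature),
                 temp_rate = as.numeric(temp_rate)),
            class = "fw_recording")
}

#' @export
print.fw_recording <- function(x, ...) {
  cat(sprintf("<fw_recording> subject %s: %.1f s at %g Hz (%d samples/axis)%s\n",
              x$subject_id, rec_duration(x), x$rate, length(x$acc_v),
              if (is.null(x$temperature)) ", no temperature"
              else sprintf(", temperature at %g Hz", x$temp_rate)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `fw_recording`.
#' @export
rec_duration <- function(rec) length(rec$acc_v) / rec$rate

#' Read a recording from the documented CSV dialect
#'
#' The canonical on-disk form is a headed CSV with columns
#' `t, acc_v, acc_ap, acc_ml[, temp]` (`t` in seconds from the start, float)
#' and an optional sidecar JSON `<path>.json` carrying `subject_id`,
#' `start_time` (ISO-8601) and the nominal `rate`.  The sampling rate is
#' inferred from the time column and checked for uniformity.
#'
#' @param path CSV file path.
#' @param tol relative tolerance on inter-sample spacing (default 1%).
#' @return An `fw_recording`.
#' @export
read_recording <- function(path, tol = 0.01) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  dt <- data.table::fread(path)
  need <- c("t", "acc_v", "acc_ap", "acc_ml")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("recording CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  tcol <- dt$t
  if (length(tcol) < 2L) stop("recording must contain at least 2 samples")
  d <- diff(tcol)
  md <- median(d)
  if (md <= 0 || any(d <= 0)) stop("time column must be strictly increasing")
  if (max(abs(d - md)) > tol * md)
    stop("non-uniform sampling: inter-sample spacing deviates more than ",
         tol * 100, "% from the median interval")
  meta <- list(subject_id = "S1",
               start_time = "2023-05-01T00:00:00Z", rate = 1 / md)
  side <- paste0(path, ".json")
  if (file.exists(side))
    meta <- modifyList(meta, jsonlite::read_json(side, simplifyVector = TRUE))
  temp <- NULL; trate <- 1
  if ("temp" %in% names(dt)) {
    temp <- dt$temp[!is.na(dt$temp)]
    # temperature may be logged sparsely: rate follows retained samples
    trate <- length(temp) / (length(tcol) / (1 / md))
    if (!length(temp)) temp <- NULL
  }
  new_recording(dt$acc_v, dt$acc_ap, dt$acc_ml, rate = as.numeric(meta$rate),
                subject_id = meta$subject_id,
                start_time = as.POSIXct(meta$start_time, tz = "UTC",
                                        tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                       "%Y-%m-%d %H:%M:%S")),
                temperature = temp, temp_rate = trate)
}

#' Write a recording (CSV + sidecar JSON)
#'
#' @param rec an `fw_recording`.
#' @param path output CSV path; a sidecar `<path>.json` is written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- length(rec$acc_v)
  dt <- data.table::data.table(t = (seq_len(n) - 1L) / rec$rate,
                               acc_v = rec$acc_v, acc_ap = rec$acc_ap,
                               acc_ml = rec$acc_ml)
  if (!is.null(rec$temperature)) {
    # temperature resampled onto the acceleration grid for a single table
    tt <- (seq_along(rec$temperature) - 1L) / rec$temp_rate
    dt$temp <- approx(tt, rec$temperature, xout = dt$t, rule = 2)$y
  }
  data.table::fwrite(dt, path)
  jsonlite::write_json(list(subject_id = rec$subject_id,
                            start_time = format(rec$start_time,
                                                "%Y-%m-%dT%H:%M:%S",
                                                tz = "UTC"),
                            rate = rec$rate),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Resample a recording to a new rate
#'
#' Each axis is interpolated independently onto a uniform grid at
#' `target_rate`; duration is preserved to within one sample period.  Linear
#' interpolation is the default (monotone, artifact-free); cubic splines are
#' available via `method = "spline"`.
#'
#' @param rec an `fw_recording`.
#' @param target_rate new sampling rate in samples/s.
#' @param method `"linear"` or `"spline"`.
#' @return A resampled `fw_recording` (temperature channel untouched).
#' @export
resample_recording <- function(rec, target_rate, method = c("linear", "spline")) {
  method <- match.arg(method)
  stopifnot(target_rate > 0)
  n <- length(rec$acc_v)
  if (n == 0L) stop("cannot resample an empty recording")
  if (identical(as.numeric(target_rate), rec$rate)) return(rec)
  t_old <- (seq_len(n) - 1L) / rec$rate
  span <- (n - 1L) / rec$rate
  t_new <- seq(0, span, by = 1 / target_rate)
  interp <- function(y) {
    if (method == "linear") approx(t_old, y, xout = t_new)$y
    else spline(t_old, y, xout = t_new)$y
  }
  new_recording(interp(rec$acc_v), interp(rec$acc_ap), interp(rec$acc_ml),
                rate = target_rate, subject_id = rec$subject_id,
                start_time = rec$start_time, temperature = rec$temperature,
                temp_rate = rec$temp_rate)
}
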