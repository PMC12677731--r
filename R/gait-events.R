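#' Initial-contact detector parameters
#'
#' The vertical acceleration is detrended (centred moving average), low-pass
#' filtered, integrated to a vertical velocity, drift-corrected, and smoothed
#' with a second-derivative-of-Gaussian (Ricker) wavelet.  Initial contacts
#' are the positive peaks of the transformed signal between consecutive
#' zero-crossings.
#'
#' @param detrend_window detrending moving-average window in s.
#' @param lowpass_cutoff pre-integration low-pass cutoff in Hz (below the
#'   Nyquist frequency of the working rate).
#' @param wavelet_scale Ricker scale sigma in s; the wavelet responds most
#'   strongly near `sqrt(2)/(2*pi*sigma)` Hz, ~2 Hz step content by default.
#' @param hp_cutoff post-integration drift-removal high-pass corner in Hz.
#' @param amp_fraction peaks below `amp_fraction` times the maximum
#'   magnitude of the transformed signal are discarded (suppresses filter
#'   side lobes and noise-only segments).
#' @param amp_floor absolute amplitude floor on the transformed signal, in
#'   the integrated signal's units (m/s).
#' @return A list of class `fw_ic_params`.
#' @export
ic_params <- function(detrend_window = 1, lowpass_cutoff = 10,
                      wavelet_scale = 0.11, hp_cutoff = 0.1,
                      amp_fraction = 0.25, amp_floor = 0.01) {
  stopifnot(detrend_window > 0, lowpass_cutoff > 0, wavelet_scale > 0,
            hp_cutoff > 0, amp_fraction >= 0, amp_floor >= 0)
  structure(list(detrend_window = detrend_window,
                 lowpass_cutoff = lowpass_cutoff,
                 wavelet_scale = wavelet_scale, hp_cutoff = hp_cutoff,
                 amp_fraction = amp_fraction, amp_floor = amp_floor),
            class = "fw_ic_params")
}

#' Detect foot initial contacts from vertical acceleration
#'
#' @param acc_v vertical acceleration series in g (gravity included).
#' @param rate sampling rate in samples/s.
#' @param params see [ic_params()].
#' @return Numeric vector of initial-contact times in s from the start of
#'   `acc_v`, strictly increasing.  Series shorter than the filter warm-up
#'   (~2 s) return an empty vector with a warning.
#' @export
detect_initial_contacts <- function(acc_v, rate, params = ic_params()) {
  stopifnot(rate > 0, params$lowpass_cutoff < rate / 2)
  if (length(acc_v) < 2 * rate) {
    warning("signal shorter than detector warm-up; no initial contacts")
    return(numeric(0))
  }
  dt <- 1 / rate
  # 1. detrend: remove gravity and posture drift
  x <- acc_v - moving_average(acc_v, round(params$detrend_window * rate))
  # 2. low-pass the impact band
  x <- lowpass(x, rate, params$lowpass_cutoff)
  # 3. integrate to vertical velocity (m/s), 4. kill integration drift
  v <- cumtrapz(x * 9.81, dt)
  v <- highpass_ma(v, rate, params$hp_cutoff)
  # 5. zero-phase Ricker smoothing
  w <- cwt_ricker(v, rate, params$wavelet_scale)
  thr <- max(params$amp_floor, params$amp_fraction * max(abs(w)))
  peaks_between_zero_crossings(w, rate, thr)
}

# Positive peaks of w lying between two consecutive zero-crossings: one
# candidate per positive lobe that is bounded by crossings on both sides.
peaks_between_zero_crossings <- function(w, rate, thr = 0) {
  r <- rle(w > 0)
  nr <- length(r$lengths)
  if (nr < 3L) return(numeric(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  cand <- cand[cand > 1L & cand < nr] # interior lobes only
  out <- numeric(length(cand))
  np <- 0L
  for (j in cand) {
    seg <- w[starts[j]:ends[j]]
    pk <- which.max(seg)
    if (seg[pk] >= thr) {
      np <- np + 1L
      out[np] <- (starts[j] + pk - 2L) / rate
    }
  }
  out[seq_len(np)]
}

#' Step-peak detector parameters
#'
#' The triaxial acceleration norm is detrended and low-pass filtered with a
#' linear-phase FIR (default cutoff 3.2 Hz, applied centred so peak times
#' carry no group delay); step-related peaks are then selected with adaptive
#' amplitude and peak-to-peak duration thresholds.
#'
#' @param fir_cutoff FIR low-pass cutoff in Hz.
#' @param amp_floor absolute minimum peak amplitude in g.
#' @param amp_fraction adaptive threshold as a fraction of the rolling median
#'   amplitude of recently accepted peaks.
#' @param adapt_window_s look-back window for the adaptive threshold in s.
#' @param pp_min,pp_max peak-to-peak duration bounds in s; candidates closer
#'   than `pp_min` are resolved in favour of the larger amplitude.
#' @return A list of class `fw_step_params`.
#' @export
step_params <- function(fir_cutoff = 3.2, amp_floor = 0.05,
                        amp_fraction = 0.4, adapt_window_s = 5,
                        pp_min = 0.35, pp_max = 2.3) {
  stopifnot(fir_cutoff > 0, 0 < pp_min, pp_min < pp_max,
            amp_fraction > 0, amp_fraction <= 1)
  structure(list(fir_cutoff = fir_cutoff, amp_floor = amp_floor,
                 amp_fraction = amp_fraction, adapt_window_s = adapt_window_s,
                 pp_min = pp_min, pp_max = pp_max), class = "fw_step_params")
}

#' Detect candidate step peaks on the acceleration norm
#'
#' @param acc_norm norm of the triaxial acceleration in g.
#' @param rate sampling rate in samples/s.
#' @param params see [step_params()].
#' @return data.frame with `time` (s) and `amplitude` (g above the local
#'   baseline), times strictly increasing; zero rows when nothing exceeds
#'   the thresholds.
#' @export
detect_step_peaks <- function(acc_norm, rate, params = step_params()) {
  stopifnot(rate > 0)
  empty <- data.frame(time = numeric(0), amplitude = numeric(0))
  if (length(acc_norm) < 2 * rate) return(empty)
  x <- acc_norm - moving_average(acc_norm, round(1 * rate))
  x <- lowpass(x, rate, params$fir_cutoff)
  idx <- local_maxima(x)
  idx <- idx[x[idx] > 0]
  if (!length(idx)) return(empty)
  tt <- (idx - 1L) / rate
  amp <- x[idx]
  # causal adaptive amplitude threshold: fraction of the median amplitude of
  # peaks accepted in the preceding window, never below the absolute floor
  keep <- logical(length(idx))
  acc_t <- numeric(length(idx)); acc_a <- numeric(length(idx))
  na <- 0L; lo <- 1L
  for (i in seq_along(idx)) {
    while (lo <= na && acc_t[lo] < tt[i] - params$adapt_window_s) lo <- lo + 1L
    thr <- if (lo <= na)
      max(params$amp_floor, params$amp_fraction * median(acc_a[lo:na]))
    else params$amp_floor
    if (amp[i] >= thr) {
      keep[i] <- TRUE
      na <- na + 1L
      acc_t[na] <- tt[i]; acc_a[na] <- amp[i]
    }
  }
  ii <- idx[keep]; tt <- tt[keep]; amp <- amp[keep]
  if (!length(tt)) return(empty)
  # minimum peak-to-peak spacing: larger amplitude wins
  m <- ceiling(params$pp_min * rate) - 1L
  occ <- logical(length(x))
  sel <- logical(length(tt))
  for (i in order(-amp, tt)) {
    win <- max(1L, ii[i] - m):min(length(x), ii[i] + m)
    if (!any(occ[win])) {
      sel[i] <- TRUE
      occ[ii[i]] <- TRUE
    }
  }
  o <- order(tt[sel])
  data.frame(time = tt[sel][o], amplitude = amp[sel][o])
}
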