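#' Assemble step events into walking bouts
#'
#' A walking bout is a maximal run of 2 or more consecutive steps in which
#' every inter-step gap is at most 1.5 s plus the average step duration of
#' the bout built so far (a causal running mean of the bout's previous
#' intervals; `default_step` is used before the first interval exists).
#' Singleton steps are discarded.
#'
#' @param step_times sorted step-event times in s.
#' @param default_step prior mean step duration in s, used for the first gap.
#' @param max_gap fixed slack added to the average step duration (s).
#' @return List of numeric vectors, one per bout, each of length >= 2.
#' @export
assemble_bouts <- function(step_times, default_step = 0.7, max_gap = 1.5) {
  n <- length(step_times)
  if (n && is.unsorted(step_times)) stop("step_times must be sorted")
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    sum_int <- 0
    while (j < n) {
      mean_step <- if (j > i) sum_int / (j - i) else default_step
      gap <- step_times[j + 1L] - step_times[j]
      if (gap > max_gap + mean_step) break
      sum_int <- sum_int + gap
      j <- j + 1L
    }
    if (j > i) out[[length(out) + 1L]] <- step_times[i:j]
    i <- j + 1L
  }
  out
}

#' Duration and cadence of one bout
#'
#' Duration is the interval from the first to the last initial contact;
#' cadence is the interval-based step frequency `60 * (n - 1) / duration`
#' (the first-to-last interval contains `n - 1` steps).
#'
#' @param step_times >= 2 strictly increasing step times in s.
#' @return list with `duration` (s) and `cadence` (steps/min).
#' @export
compute_bout_timing <- function(step_times) {
  stopifnot(length(step_times) >= 2L)
  duration <- step_times[length(step_times)] - step_times[1L]
  if (duration <= 0) stop("degenerate bout: duplicate step times")
  list(duration = duration,
       cadence = 60 * (length(step_times) - 1L) / duration)
}

#' Inverted-pendulum parameters for step-length estimation
#'
#' During one step the trunk vaults over the stance leg like an inverted
#' pendulum of length `l` (sensor height above the ground); the vertical
#' excursion `h` of the centre of mass then fixes the step length as
#' `K * 2 * sqrt(2 * l * h - h^2)`, where `K` corrects the model's known
#' underestimation (impaired gait included).
#'
#' @param l pendulum length in m; when `NULL`, derived from `body_height_cm`
#'   as `leg_fraction * height`, or 0.90 m when no height is known.
#' @param K dimensionless correction factor (default 1.25).
#' @param leg_fraction fraction of body height giving `l` (default 0.53).
#' @param body_height_cm optional body height in cm.
#' @param hp_cutoff drift-removal corner frequency in Hz for long windows.
#' @return list of class `fw_pendulum_params`.
#' @export
pendulum_params <- function(l = NULL, K = 1.25, leg_fraction = 0.53,
                            body_height_cm = NULL, hp_cutoff = 0.1) {
  if (is.null(l))
    l <- if (is.null(body_height_cm)) 0.90
         else leg_fraction * body_height_cm / 100
  stopifnot(l > 0, K > 0)
  structure(list(l = l, K = K, leg_fraction = leg_fraction,
                 hp_cutoff = hp_cutoff), class = "fw_pendulum_params")
}

#' Per-step lengths from the inverted-pendulum model
#'
#' For each initial-contact-to-initial-contact window the vertical
#' acceleration is doubly integrated; integration drift is removed per
#' window by subtracting the line through the window endpoints, and the
#' vertical excursion `h = max - min` feeds the pendulum formula.  Steps whose
#' excursion reaches the pendulum length are flagged and clamped to
#' `h = 0.9 * l` with a warning.
#'
#' @param acc_v vertical acceleration in g covering the bout (the series is
#'   indexed from `t = 0` at its own first sample).
#' @param rate sampling rate in samples/s.
#' @param step_times initial-contact times in s on the same clock as
#'   `acc_v`; `n` times give `n - 1` step windows.
#' @param params see [pendulum_params()].
#' @return numeric vector of `length(step_times) - 1` step lengths in m.
#' @export
estimate_step_lengths <- function(acc_v, rate, step_times,
                                  params = pendulum_params()) {
  stopifnot(length(step_times) >= 2L, rate > 0)
  l <- params$l
  dt <- 1 / rate
  n <- length(acc_v)
  # remove gravity/posture offset over the whole bout, then integrate twice
  a <- (acc_v - mean(acc_v)) * 9.81
  vel <- cumtrapz(a, dt)
  pos <- cumtrapz(vel - mean(vel), dt)
  vapply(seq_len(length(step_times) - 1L), function(k) {
    i0 <- max(1L, floor(step_times[k] * rate) + 1L)
    i1 <- min(n, ceiling(step_times[k + 1L] * rate) + 1L)
    if (i1 - i0 < 2L) return(0)
    z <- pos[i0:i1]
    # drift correction: remove the line through the window endpoints (for a
    # closed pendulum arc both ends sit at the same height, so this is
    # exact; a least-squares line would tilt against the arc itself)
    m <- length(z)
    z <- z - (z[1L] + (z[m] - z[1L]) * (seq_len(m) - 1L) / (m - 1L))
    h <- max(z) - min(z)
    if (h >= l) {
      warning("vertical excursion exceeds pendulum length; clamping")
      h <- 0.9 * l
    }
    params$K * 2 * sqrt(pmax(0, 2 * l * h - h^2))
  }, numeric(1))
}

#' Summarise a bout into its gait metrics
#'
#' Cadence and duration come from the initial contacts; mean step length is
#' the average across the bout's steps; speed is `cadence / 60 *
#' mean_step_length` and distance is `duration * speed` (definitional
#' identities, not estimates).
#'
#' @param step_times >= 2 strictly increasing initial-contact times (s,
#'   recording clock).
#' @param step_lengths per-step lengths in m (`length(step_times) - 1`, or
#'   any non-empty vector which is then averaged as-is).
#' @param day_index calendar-day assignment of the bout (day of its start).
#' @return One-row data.frame: `start`, `end`, `duration`, `n_steps`,
#'   `cadence`, `mean_step_length`, `speed`, `distance`, `day_index`, and a
#'   `step_times` list-column.
#' @export
summarize_bout <- function(step_times, step_lengths, day_index = 1L) {
  tm <- compute_bout_timing(step_times)
  msl <- mean(step_lengths)
  speed <- tm$cadence / 60 * msl
  data.frame(start = step_times[1L], end = step_times[length(step_times)],
             duration = tm$duration, n_steps = length(step_times),
             cadence = tm$cadence, mean_step_length = msl, speed = speed,
             distance = tm$duration * speed, day_index = as.integer(day_index),
             step_times = I(list(step_times)))
}
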