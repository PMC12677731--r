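#' Specify a synthetic gait protocol
#'
#' A protocol is the stated world a synthetic recording realises: walking
#' bouts with known start, step count, cadence and step length; a wear
#' schedule; sensor noise; and the landing-impact amplitude.  All derived
#' ground truth follows from it by construction.
#'
#' @param bouts data.frame with columns `start` (s), `n_steps`, `cadence`
#'   (steps/min, in (30, 200)) and `step_length` (m, < 2).
#' @param duration recording duration in s.
#' @param wear data.frame `start`, `end`, `worn`; default worn throughout.
#' @param noise_sd white acceleration noise SD in g (per axis).
#' @param body_height_cm body height (informs the pendulum length).
#' @param ic_spike_amp landing-impact half-sine amplitude in g.
#' @param seed integer seed for the noise.
#' @return list of class `fw_protocol`.
#' @export
gait_protocol <- function(bouts, duration,
                          wear = data.frame(start = 0, end = duration,
                                            worn = TRUE),
                          noise_sd = 0, body_height_cm = 168.8,
                          ic_spike_amp = 0.4, seed = 1L) {
  stopifnot(all(c("start", "n_steps", "cadence", "step_length") %in%
                names(bouts)))
  stopifnot(all(bouts$cadence > 30 & bouts$cadence < 200),
            all(bouts$step_length < 2), all(bouts$n_steps >= 2),
            noise_sd >= 0, duration > 0)
  if (nrow(bouts) > 1L) {
    ends <- bouts$start + (bouts$n_steps - 1) * 60 / bouts$cadence
    o <- order(bouts$start)
    if (any(bouts$start[o][-1L] < ends[o][-nrow(bouts)] + 1))
      stop("bouts overlap (or are separated by less than 1 s)")
  }
  structure(list(bouts = bouts[order(bouts$start), , drop = FALSE],
                 duration = duration, wear = wear, noise_sd = noise_sd,
                 body_height_cm = body_height_cm,
                 ic_spike_amp = ic_spike_amp, seed = as.integer(seed)),
            class = "fw_protocol")
}

# Vertical CoM excursion h realising a target step length under the
# pendulum model: K * 2 * sqrt(2 l h - h^2) = L  =>  h = l - sqrt(l^2 - (L/2K)^2)
solve_excursion <- function(step_length, l, K) {
  q <- (step_length / (2 * K))^2
  if (q >= l^2)
    stop("step length ", step_length,
         " m unreachable for pendulum length ", l, " m")
  l - sqrt(l^2 - q)
}

#' Synthesize an accelerometer recording from a protocol
#'
#' The vertical axis carries gravity plus, per bout, the second time
#' derivative of a sinusoidal vertical centre-of-mass trajectory whose
#' excursion realises the protocol's step length under the pendulum model,
#' phased so that the vertical velocity peaks at each true initial contact
#' (the convention the wavelet detector reports), plus a 50 ms half-sine
#' landing transient at each initial contact, plus white noise.  The
#' temperature channel follows the wear schedule with exponential
#' transitions between ambient (~21 degC) and skin (~32 degC) temperature.
#'
#' @param protocol see [gait_protocol()].
#' @param rate acceleration sampling rate in samples/s.
#' @param pendulum pendulum parameters used to invert the step length; the
#'   default derives `l` from the protocol's body height.
#' @param temp_rate temperature sampling rate in samples/s.
#' @param temp_tau temperature transition time constant in s.
#' @return list with `recording` (an `fw_recording`) and `truth`, a list
#'   holding `ic_times`, `step_peak_times` (analytic maxima of the
#'   band-limited norm), a per-bout `bouts` table with true metrics, and
#'   the wear schedule.
#' @export
synthesize_recording <- function(protocol, rate = 100,
                                 pendulum = pendulum_params(
                                   body_height_cm = protocol$body_height_cm),
                                 temp_rate = 1, temp_tau = 120) {
  n <- round(protocol$duration * rate)
  tt <- (seq_len(n) - 1L) / rate
  acc_v <- rep(1, n)
  ic_times <- numeric(0)
  peak_times <- numeric(0)
  l <- pendulum$l; K <- pendulum$K
  bt <- protocol$bouts
  truth_bouts <- vector("list", nrow(bt))
  for (b in seq_len(nrow(bt))) {
    Tstep <- 60 / bt$cadence[b]
    ns <- bt$n_steps[b]
    s0 <- bt$start[b]
    ics <- s0 + (seq_len(ns) - 1L) * Tstep
    h <- solve_excursion(bt$step_length[b], l, K)
    # z(t) = (h/2) sin(2 pi (t - s0)/T) over [s0 - T/4, last IC + T/4]:
    # velocity maxima fall exactly on the ICs, excursion per IC-to-IC
    # window is h, and the velocity is continuous (zero) at both ends.
    w0 <- s0 - Tstep / 4
    w1 <- ics[ns] + Tstep / 4
    idx <- max(1L, ceiling(w0 * rate) + 1L):min(n, floor(w1 * rate) + 1L)
    om <- 2 * pi / Tstep
    # smooth onset/offset envelope over the lead-in/out quarter periods
    # (outside all IC-to-IC windows) to avoid a hard spectral edge
    env <- rep(1, length(idx))
    ramp_in <- tt[idx] < s0
    env[ramp_in] <- sin(pi / 2 * (tt[idx][ramp_in] - w0) / (Tstep / 4))^2
    ramp_out <- tt[idx] > ics[ns]
    env[ramp_out] <- sin(pi / 2 * (w1 - tt[idx][ramp_out]) / (Tstep / 4))^2
    acc_v[idx] <- acc_v[idx] -
      env * (h / 2) * om^2 * sin(om * (tt[idx] - s0)) / 9.81
    # landing transient: half-sine, 50 ms, centred on each IC
    for (ic in ics) {
      ii <- max(1L, ceiling((ic - 0.025) * rate) + 1L):
            min(n, floor((ic + 0.025) * rate) + 1L)
      acc_v[ii] <- acc_v[ii] +
        protocol$ic_spike_amp * cos(pi * (tt[ii] - ic) / 0.05)
    }
    ic_times <- c(ic_times, ics)
    # norm maxima of the band-limited component: where sin = -1
    if (ns >= 2L)
      peak_times <- c(peak_times, s0 + 0.75 * Tstep + (seq_len(ns - 1L) - 1L) * Tstep)
    duration <- (ns - 1L) * Tstep
    speed <- bt$cadence[b] / 60 * bt$step_length[b]
    truth_bouts[[b]] <- data.frame(
      start = ics[1L], end = ics[ns], duration = duration, n_steps = ns,
      cadence = bt$cadence[b], mean_step_length = bt$step_length[b],
      speed = speed, distance = duration * speed)
  }
  set.seed(protocol$seed)
  if (protocol$noise_sd > 0) {
    acc_v <- acc_v + rnorm(n, 0, protocol$noise_sd)
    acc_ap <- rnorm(n, 0, protocol$noise_sd)
    acc_ml <- rnorm(n, 0, protocol$noise_sd)
  } else {
    acc_ap <- numeric(n); acc_ml <- numeric(n)
  }
  temp <- synthesize_temperature(protocol$wear, protocol$duration,
                                 temp_rate, temp_tau)
  rec <- new_recording(acc_v, acc_ap, acc_ml, rate = rate,
                       subject_id = "SYN1", temperature = temp,
                       temp_rate = temp_rate)
  list(recording = rec,
       truth = list(ic_times = ic_times, step_peak_times = peak_times,
                    bouts = do.call(rbind, truth_bouts),
                    wear = protocol$wear))
}

# Temperature path: first-order relaxation towards 32 degC (worn) or
# 21 degC (ambient), per the wear schedule.
synthesize_temperature <- function(wear, duration, temp_rate, tau,
                                   t_skin = 32, t_ambient = 21) {
  nt <- round(duration * temp_rate)
  ts <- (seq_len(nt) - 1L) / temp_rate
  worn_at <- rep(TRUE, nt)
  for (i in seq_len(nrow(wear)))
    worn_at[ts >= wear$start[i] & ts < wear$end[i]] <- wear$worn[i]
  target <- ifelse(worn_at, t_skin, t_ambient)
  temp <- numeric(nt)
  temp[1L] <- target[1L]
  al <- exp(-1 / (temp_rate * tau))
  for (i in seq_len(nt - 1L))
    temp[i + 1L] <- target[i + 1L] + (temp[i] - target[i + 1L]) * al
  temp
}

#' Cohort simulation parameters
#'
#' Each gait metric is drawn from the generative reading of the regression
#' model: `y = exp(beta0 + beta1 * (age - 70)^beta_p) * eps` with `eps`
#' gamma-distributed (mean 1, variance `phi`).  Ages follow a right-skewed
#' shifted exponential on [70, 105]; SPPB decreases with age through a
#' logistic mean curve.  Default metric parameters are fixed package
#' choices producing cohort-plausible levels (about 6500 steps/day, fast
#' speed about 1.15 m/s, fast cadence about 106 steps/min at age 70); men
#' get a higher level for steps, speed and distance and a slightly lower
#' cadence.
#'
#' @param n_female,n_male subjects per sex.
#' @param metrics named list of per-metric parameter lists
#'   `(beta0, beta1, beta_p, phi)`; defaults supplied.
#' @param male_shift named vector of additive `beta0` shifts for men.
#' @param age_rate rate of the exponential age excess (mean 1/rate years).
#' @param seed integer seed.
#' @return list of class `fw_cohort_sim`.
#' @export
cohort_sim_params <- function(n_female = 100, n_male = 100,
                              metrics = NULL, male_shift = NULL,
                              age_rate = 1 / 7.4, seed = 1L) {
  if (is.null(metrics))
    metrics <- list(
      daily_steps  = list(beta0 = 8.78, beta1 = -0.02,  beta_p = 1.6, phi = 0.25),
      fast_speed   = list(beta0 = 0.14, beta1 = -0.005, beta_p = 1.5, phi = 0.04),
      mode_speed   = list(beta0 = -0.16, beta1 = -0.005, beta_p = 1.5, phi = 0.06),
      fast_cadence = list(beta0 = 4.66, beta1 = -0.001, beta_p = 1.3, phi = 0.005),
      mode_cadence = list(beta0 = 4.50, beta1 = -0.0005, beta_p = 1.5, phi = 0.01),
      max_distance = list(beta0 = 6.55, beta1 = -0.03,  beta_p = 1.3, phi = 0.8))
  if (is.null(male_shift))
    male_shift <- c(daily_steps = 0.13, fast_speed = 0.09, mode_speed = 0.12,
                    fast_cadence = -0.04, mode_cadence = -0.06,
                    max_distance = 0.35)
  stopifnot(all(vapply(metrics, function(m) m$phi > 0, logical(1))))
  structure(list(n_female = n_female, n_male = n_male, metrics = metrics,
                 male_shift = male_shift, age_rate = age_rate,
                 seed = as.integer(seed)), class = "fw_cohort_sim")
}

#' Synthesize a cohort table from the gamma model
#'
#' @param params see [cohort_sim_params()].
#' @return list with `cohort` (data.frame: `subject_id`, `sex`, `age`,
#'   `sppb`, `height_cm`, one column per metric) and `truth` (the
#'   generating parameters).
#' @export
synthesize_cohort <- function(params = cohort_sim_params()) {
  set.seed(params$seed)
  n <- params$n_female + params$n_male
  sex <- c(rep("female", params$n_female), rep("male", params$n_male))
  age <- 70 + rexp(n, params$age_rate)
  while (any(age > 105)) # resample the truncated tail
    age[age > 105] <- 70 + rexp(sum(age > 105), params$age_rate)
  sppb_mean <- 12 * plogis((88 - age) / 6)
  sppb <- pmin(12, pmax(0, round(sppb_mean + rnorm(n, 0, 2))))
  height <- ifelse(sex == "male", rnorm(n, 175, 6), rnorm(n, 162, 6))
  x <- age - 70
  cohort <- data.frame(subject_id = sprintf("SYN%04d", seq_len(n)),
                       sex = sex, age = age, sppb = sppb,
                       height_cm = round(height, 1))
  for (m in names(params$metrics)) {
    p <- params$metrics[[m]]
    b0 <- p$beta0 + ifelse(sex == "male", params$male_shift[[m]], 0)
    mu <- exp(b0 + p$beta1 * x^p$beta_p)
    cohort[[m]] <- mu * rgamma(n, shape = 1 / p$phi, scale = p$phi)
  }
  list(cohort = cohort, truth = params)
}

#' Configuration for a synthetic "week" at desk scale
#'
#' Real 7 x 24 h recordings at 100 Hz are too large for tests, so the week
#' is compressed: each "day" lasts `day_seconds` and the valid-day rule is
#' applied proportionally (worn fraction >= 18/24).  Bout durations follow
#' the four duration categories with most bouts at or under 10 s, matching
#' the qualitative structure of free-living walking in older adults.
#'
#' @param n_days number of days.
#' @param day_seconds length of a compressed day in s.
#' @param rate acceleration sampling rate in samples/s.
#' @param walk_fraction target fraction of worn time spent walking.
#' @param cat_probs probabilities of the four bout-duration categories.
#' @param cadence_mean,cadence_sd cadence distribution (steps/min).
#' @param step_length_mean,step_length_sd step-length distribution (m).
#' @param noise_sd acceleration noise SD in g.
#' @param nonwear_day index of a day given a long non-wear block (makes it
#'   invalid under the 18/24 rule); `0` disables it.
#' @param nonwear_fraction fraction of that day spent off-body.
#' @return list of class `fw_week_config`.
#' @export
week_config <- function(n_days = 7, day_seconds = 1800, rate = 100,
                        walk_fraction = 0.30,
                        cat_probs = c(0.63, 0.25, 0.08, 0.04),
                        cadence_mean = 100, cadence_sd = 10,
                        step_length_mean = 0.60, step_length_sd = 0.07,
                        noise_sd = 0.02, nonwear_day = 3,
                        nonwear_fraction = 0.5) {
  stopifnot(n_days >= 1, day_seconds > 60, abs(sum(cat_probs) - 1) < 1e-9)
  structure(as.list(environment()), class = "fw_week_config")
}

#' Synthesize a multi-day recording with ground truth
#'
#' Draws per-day walking bouts (category-distributed durations, normal
#' cadence and step length), inserts a non-wear block on one day, and
#' renders the whole week with [synthesize_recording()].
#'
#' @param config see [week_config()].
#' @param seed integer seed controlling both the protocol draw and the
#'   rendered noise.
#' @return list with `recording`, `truth` (as in [synthesize_recording()],
#'   plus `daily_steps`, `day_valid` and `day_seconds`), and `protocol`.
#' @export
synthesize_week <- function(config = week_config(), seed = 1L) {
  set.seed(seed)
  ds <- config$day_seconds
  bout_rows <- list()
  wear_rows <- list()
  for (day in seq_len(config$n_days)) {
    d0 <- (day - 1) * ds
    nonwear <- day == config$nonwear_day
    # off-body block in the middle of the non-wear day
    if (nonwear) {
      nw0 <- d0 + 0.25 * ds
      nw1 <- nw0 + config$nonwear_fraction * ds
      wear_rows[[length(wear_rows) + 1L]] <-
        data.frame(start = nw0, end = nw1, worn = FALSE)
    }
    budget <- config$walk_fraction * ds * (if (nonwear) 1 - config$nonwear_fraction else 1)
    t_cur <- d0 + 30 + rexp(1, 1 / 20)
    walked <- 0
    while (walked < budget && t_cur < d0 + ds - 130) {
      k <- sample.int(4L, 1L, prob = config$cat_probs)
      dur <- switch(k, runif(1, 3, 10), runif(1, 10, 30),
                    runif(1, 30, 60), runif(1, 60, 120))
      cad <- min(140, max(60, rnorm(1, config$cadence_mean, config$cadence_sd)))
      sl <- min(0.85, max(0.30, rnorm(1, config$step_length_mean,
                                      config$step_length_sd)))
      Tstep <- 60 / cad
      ns <- max(2L, floor(dur / Tstep) + 1L) # realised duration <= drawn
      end <- t_cur + (ns - 1L) * Tstep
      if (end > d0 + ds - 10) break
      if (nonwear && end > nw0 - 5 && t_cur < nw1 + 5) {
        t_cur <- nw1 + 10 # skip past the off-body block
        next
      }
      bout_rows[[length(bout_rows) + 1L]] <-
        data.frame(start = t_cur, n_steps = ns, cadence = cad,
                   step_length = sl)
      walked <- walked + (ns - 1L) * Tstep
      t_cur <- end + 5 + rexp(1, 1 / 25)
    }
  }
  bouts <- do.call(rbind, bout_rows)
  duration <- config$n_days * ds
  wear <- rbind(data.frame(start = 0, end = duration, worn = TRUE),
                do.call(rbind, wear_rows))
  proto <- gait_protocol(bouts, duration = duration, wear = wear,
                         noise_sd = config$noise_sd,
                         seed = seed + 1000L)
  syn <- synthesize_recording(proto, rate = config$rate,
                              temp_tau = ds / 30)
  day_of <- function(t) pmin(config$n_days, floor(t / ds) + 1L)
  tb <- syn$truth$bouts
  daily <- vapply(seq_len(config$n_days),
                  function(d) sum(tb$n_steps[day_of(tb$start) == d]),
                  numeric(1))
  worn_frac <- vapply(seq_len(config$n_days), function(d) {
    nw <- wear_rows
    off <- 0
    for (w in nw) off <- off +
        max(0, min(w$end, d * ds) - max(w$start, (d - 1) * ds))
    1 - off / ds
  }, numeric(1))
  syn$truth$bouts$day_index <- day_of(tb$start)
  syn$truth$daily_steps <- daily
  syn$truth$day_valid <- worn_frac >= 18 / 24
  syn$truth$day_seconds <- ds
  c(syn, list(protocol = proto))
}
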