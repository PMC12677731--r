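# Independent oracles and small utilities shared across the suite.

# Brute-force bout grouping: extend each group step by step, recomputing the
# mean step duration from scratch with mean(diff(.)); keeps maximal groups
# of >= 2.  Deliberately written differently from assemble_bouts().
oracle_bouts <- function(st, default_step = 0.7, max_gap = 1.5) {
  groups <- list()
  cur <- numeric(0)
  for (t in st) {
    if (!length(cur)) {
      cur <- t
    } else {
      ms <- if (length(cur) >= 2) mean(diff(cur)) else default_step
      if (t - cur[length(cur)] <= max_gap + ms) {
        cur <- c(cur, t)
      } else {
        if (length(cur) >= 2) groups[[length(groups) + 1L]] <- cur
        cur <- t
      }
    }
  }
  if (length(cur) >= 2) groups[[length(groups) + 1L]] <- cur
  groups
}

# Greedy one-to-one event matching inside a +/- window; returns the F1.
event_f1 <- function(detected, truth, window = 0.15) {
  if (!length(detected) || !length(truth)) return(0)
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (t in detected) {
    j <- which(!used & abs(truth - t) <= window)
    if (length(j)) {
      used[j[which.min(abs(truth[j] - t))]] <- TRUE
      tp <- tp + 1L
    }
  }
  prec <- tp / length(detected)
  rec <- tp / length(truth)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Single-bout protocol with noise calibrated to a target SNR (dB) of the
# dynamic vertical component; snr = Inf means noise-free.
snr_protocol <- function(cadence, step_length, n_steps = 30, snr = Inf,
                         seed = 42L, rate = 100) {
  Tstep <- 60 / cadence
  dur <- 5 + (n_steps - 1) * Tstep + 5
  bt <- data.frame(start = 5, n_steps = n_steps, cadence = cadence,
                   step_length = step_length)
  nsd <- 0
  if (is.finite(snr)) {
    clean <- synthesize_recording(gait_protocol(bt, dur, noise_sd = 0),
                                  rate = rate)
    dyn <- clean$recording$acc_v - 1
    nsd <- sqrt(mean(dyn^2)) / 10^(snr / 20)
  }
  gait_protocol(bt, dur, noise_sd = nsd, seed = seed)
}

# Per-observation gamma log-density written from the closed form, as an
# independent check on gamma_loglik().
gamma_logdens_direct <- function(y, mu, phi) {
  a <- 1 / phi
  -lgamma(a) - a * log(phi * mu) + (a - 1) * log(y) - y / (phi * mu)
}
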