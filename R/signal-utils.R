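# Internal DSP helpers shared by the wear and gait-event detectors.
# All filters are zero-phase (symmetric kernels applied centred), so event
# times read off filtered signals carry no group delay.

# Centred moving average with truncated windows at the edges.
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L || length(x) == 0L) return(x)
  half <- n %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Linear convolution, same-size output, symmetric odd-length kernel.
# Edges are handled by reflecting the signal, which avoids step artefacts
# at the boundaries of short windows.
conv_same <- function(x, k) {
  nk <- length(k)
  stopifnot(nk %% 2L == 1L)
  half <- (nk - 1L) %/% 2L
  n <- length(x)
  if (n == 0L) return(x)
  pad <- min(half, n - 1L)
  left <- if (pad > 0) x[(pad + 1L):2L] else numeric(0)
  right <- if (pad > 0) x[(n - 1L):(n - pad)] else numeric(0)
  if (pad < half) { # very short signals: extend with edge values
    left <- c(rep(x[1L], half - pad), left)
    right <- c(right, rep(x[n], half - pad))
  }
  xp <- c(left, x, right)
  np <- length(xp)
  # FFT-based convolution; kernels are a few hundred taps, signals up to 1e6+
  nfft <- stats::nextn(np + nk - 1L, 2L)
  X <- fft(c(xp, rep(0, nfft - np)))
  K <- fft(c(k, rep(0, nfft - nk)))
  y <- Re(fft(X * K, inverse = TRUE)) / nfft
  y[(2L * half + 1L):(2L * half + n)]
}

# Hamming-windowed-sinc low-pass FIR kernel (odd length => zero phase).
sinc_lowpass_kernel <- function(rate, cutoff, taps = NULL) {
  stopifnot(cutoff > 0, cutoff < rate / 2)
  if (is.null(taps)) taps <- round(3 * rate / cutoff)
  taps <- as.integer(taps)
  if (taps %% 2L == 0L) taps <- taps + 1L
  taps <- max(taps, 5L)
  m <- (taps - 1L) / 2
  t <- (-m):m
  fc <- cutoff / rate
  h <- 2 * fc * sinc_fun(2 * fc * t)
  w <- 0.54 + 0.46 * cos(pi * t / m) # Hamming
  h <- h * w
  h / sum(h)
}

sinc_fun <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

lowpass <- function(x, rate, cutoff, taps = NULL) {
  conv_same(x, sinc_lowpass_kernel(rate, cutoff, taps))
}

# High-pass as the residual from a long moving average; cutoff is the
# -3 dB-ish corner of the complementary smoother (window ~ 1/cutoff s).
highpass_ma <- function(x, rate, cutoff) {
  win <- max(3L, round(rate / cutoff))
  x - moving_average(x, win)
}

# Cumulative trapezoidal integral of a uniformly sampled series.
cumtrapz <- function(x, dt) {
  if (length(x) < 2L) return(rep(0, length(x)))
  c(0, cumsum((x[-1L] + x[-length(x)]) / 2) * dt)
}

# Ricker (second-derivative-of-Gaussian, "Mexican hat") kernel.  sigma in
# seconds; the wavelet's peak response sits near f = sqrt(2)/(2*pi*sigma).
ricker_kernel <- function(rate, sigma) {
  m <- max(5L, ceiling(4 * sigma * rate))
  t <- ((-m):m) / rate
  a <- (1 - (t / sigma)^2) * exp(-t^2 / (2 * sigma^2))
  a - mean(a) # enforce zero mean so constants map to exactly zero
}

# Smooth with a Ricker wavelet at one scale (a zero-phase band-pass).
cwt_ricker <- function(x, rate, sigma) {
  k <- ricker_kernel(rate, sigma)
  conv_same(x, k / sum(abs(k)) * 2) # unit-ish passband gain
}

# Local maxima of a series (strictly greater than the neighbour on at least
# one side, not smaller on the other); returns indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
}
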