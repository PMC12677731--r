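---
title: "freewalk: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{freewalk: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freewalk)
```

This vignette is the package's own account of its methods: the models and
procedures, the tunable parameters with their defaults and why, what the
synthetic-data generator emulates (and deliberately does not), and the
numerical choices that were genuinely open. It states no empirical result
that the test suite does not itself compute.

## 1. From raw signal to walking bouts

### Wear detection

The on-device temperature drifts towards skin temperature (~32 °C) while
the sensor is worn and relaxes to ambient (~21 °C) otherwise. `detect_wear()`
smooths the temperature with a centred moving average (default **5 min**)
and classifies a sample as worn when the smoothed temperature is at least
**27 °C** (midway between settled ambient and settled skin temperature)
*or* a warming slope of at least **0.1 °C/min** is sustained for
**2 min** (catching the warm-up right after donning, before the absolute
threshold is reached). Segments shorter than **10 min** are absorbed into
their surroundings: brief temperature excursions are not don/doff events.
These thresholds are package defaults, not a claim of equivalence to any
published event-based algorithm; all are configurable via `wear_params()`.
A missing temperature channel falls back to "worn throughout" with a loud
warning, because every target-device recording carries temperature.

A **valid day** has at least 18 of 24 hours of detected wear. Calendar
days run midnight-to-midnight (UTC offset of the recording's start time);
for compressed synthetic days (below) the same rule is applied as a
fraction, worn time / day length ≥ 18/24.

### Initial contacts

`detect_initial_contacts()` implements the classic trunk-acceleration
chain: detrend (centred moving average, **1 s** — at typical cadences the
window spans one or more whole step cycles, so the step content itself is
untouched), low-pass filter (zero-phase windowed-sinc FIR, **10 Hz**),
numerically integrate to a vertical velocity (cumulative trapezoid),
remove integration drift (residual from a 10 s moving average, a ~0.1 Hz
high-pass), and smooth with a Ricker (second-derivative-of-Gaussian)
wavelet at scale **σ = 0.11 s**, whose peak response sits near
`√2/(2πσ) ≈ 2 Hz` — step-frequency content. Initial contacts are the
positive peaks of the transformed signal between consecutive
zero-crossings.

Two gate parameters were added beyond the minimal contract: candidate
peaks below **25% of the transform's maximum magnitude**, or below an
absolute floor of **0.01 m/s**, are rejected. Without a gate a constant
or noise-only signal yields arbitrarily many micro-lobes; with it, a
constant signal yields no events and an isolated transient yields at most
one. All filters are zero-phase, so detected times carry no group delay.

### Step peaks and bout assembly

For walking-bout detection the triaxial norm is detrended and low-pass
filtered with a linear-phase FIR at **3.2 Hz** (applied centred, so peak
times are unbiased), and local maxima are kept subject to an adaptive
amplitude threshold — `max(0.05 g, 0.4 × rolling median of the last 5 s
of accepted peak amplitudes)` — and a minimum peak-to-peak spacing of
**0.35 s** (closer candidates resolve to the larger amplitude). The
0.05 g floor matters: a pendulum-consistent vertical harmonic at cadence
60 with 0.3 m steps has an amplitude near 0.007 g, which no reasonable
floor admits; very slow, very short-stepped gait is therefore invisible
to the norm-based detector (see Limitations).

Bouts are maximal runs of ≥ 2 steps where each gap is at most **1.5 s
plus the average step duration**. "Average" is read causally: the running
mean of the bout's own previous intervals, seeded with **0.7 s** before
the first interval exists. The pipeline (`run_process()`) uses step peaks
to find candidate walking windows, then re-detects ICs inside each window
and re-assembles bouts from the ICs; all metrics are computed from ICs.

### Cadence and the step-count convention

With `n` ICs the first-to-last interval contains `n − 1` steps, so bout
cadence is `60·(n−1)/duration`; using `n` would inflate cadence for short
bouts. Daily step totals count each IC as one step (a 2-IC sequence
contributes 2 steps); the bout tables carry `n_steps` so users can apply
`n − 1` instead.

### Step length

The inverted-pendulum model: during one step the trunk vaults over the
stance leg, and a vertical centre-of-mass excursion `h` with pendulum
length `l` implies a step length `K·2·√(2lh − h²)`. Per IC-to-IC window
the vertical acceleration is doubly integrated and the excursion is
`max − min` of the drift-corrected position. Drift correction subtracts
the **line through the window endpoints** — exact for a closed
pendulum arc, whereas a least-squares line has a nonzero slope against a
full sine period and biases `h` by ~10%. Defaults: `l = 0.53 × body
height` when height is known, otherwise **0.90 m** (0.53 × the cohort
mean height of 168.8 cm); correction factor **K = 1.25**, the classical
compensation for the model's underestimation — configurable, and not
claimed identical to the study pipeline's impaired-gait factor. Windows
whose excursion reaches `l` are clamped to `0.9 l` with a warning.

## 2. Aggregation

Daily aggregation: mean daily steps across valid days only (days without
bouts contribute zero; no valid day propagates `NA`). Weekly aggregation
pools all bouts regardless of day validity — the source protocol
restricts only daily steps to valid days; whether its weekly metrics also
excluded invalid-day bouts is unstated, so pooling everything is the
default with `agg_config(weekly_valid_days_only = TRUE)` as the
alternative.

The **mode** of a continuous metric needs a binning choice the protocol
leaves open: histogram bins anchored at zero, width **2 steps/min** for
cadence and **0.05 m/s** for speed, reporting the midpoint of the fullest
bin with ties broken toward the lower bin. The **95th percentile** uses
linear interpolation between order statistics (position `1 + 0.95(n−1)`),
the common statistical default, as do the quartiles in `describe()`.
Duration categories close on the left: exactly 10 s is "≤ 10 s".

## 3. Cohort tests

`mann_whitney_u()` is exact (via the null distribution of U) for
`min(n) ≤ 8` without ties. Otherwise it uses a continuity-corrected
normal approximation with tie-corrected variance, sharpened — when there
are no ties — by an Edgeworth kurtosis term with the exact excess
kurtosis `−6(m² + n² + mn + m + n)/(5mn(N+1))`. The plain corrected
normal misses the exact two-sided p by up to ~0.011 at `m = n = 8`; the
Edgeworth term brings the worst case under 0.004, so the two branches
agree to < 0.01 at the hand-over boundary. `chi2_independence()` is the
plain Pearson statistic without continuity correction (the sex × SPPB
band comparison has df = 2, where no correction applies).

## 4. The power-law gamma regression

Each gait metric is strictly positive and right-skewed with roughly
multiplicative noise, hence

`y = exp(β₀ + β₁ xᵝᵖ) · ε`, `ε ~ Gamma(mean 1, variance φ)`,

equivalently `y ~ Gamma(shape 1/φ, scale φμ)`. The covariate is shifted
to its reference: `x = age − 70`, or `x = 12 − SPPB` so a perfect score
is the reference and declines are positive `x`.

**Fitting.** For a given exponent, the coefficient MLE of a log-link
gamma GLM does not involve φ, so (β₀, β₁) come from iteratively
reweighted least squares (to 1e-12) and φ from its one-dimensional ML
equation `log a − ψ(a) = mean(r − log r) − 1` with `a = 1/φ`,
`r = y/μ` (solved by bisection on `log a`). The exponent is profiled over
the grid **0.1–4.0, step 0.05**, then refined by golden-section search to
**1e-6**. Estimating φ by ML at every candidate keeps the AIC comparison
between models coherent; both models count φ, so the free-exponent model
has k = 4 parameters and the fixed one k = 3, and the comparison is
invariant to whether φ is counted at all. The free exponent is retained
only when AIC strictly improves; ties keep β_p = 1.

**Standard errors.** β₁ and β_p trade off along a likelihood ridge
(rescaling `xᵝᵖ` is nearly absorbed by β₁), so an SE that holds β_p at
its estimate understates the slope's uncertainty by an order of
magnitude. The default SE therefore comes from the expected (Fisher)
information including the exponent column `β₁ xᵝᵖ log x` — block-diagonal
with respect to φ, hence `cov = φ (GᵀG)⁻¹` with
`G = [1, xᵝᵖ, β₁ xᵝᵖ log x]`. The parameter-recovery tests measure ±2 SE
coverage of 94–97% under this choice; the held-exponent formula remains
available (`fit_config(se_method = "fixed_exponent")`).

**Orchestration.** `run_fit()` fits women and men separately, applies the
singleton-age exclusion (only representative of a (sex, integer age)
cell) for age models, skips strata under 10 subjects with a warning, and
writes percent-change tables at the covariate steps of interest
(70→71, 80→81, 90→91 years; 12→11, 6→5, 1→0 SPPB points).

## 5. What the synthetic generator does (and does not) emulate

`synthesize_recording()` renders, per bout, a sinusoidal vertical
centre-of-mass trajectory whose excursion `h` solves
`K·2·√(2lh − h²) = target step length` — so the pipeline's pendulum
inversion can recover the protocol's step length exactly — plus a 50 ms
half-sine landing transient (default **0.4 g**) at each true IC, plus
white noise per axis; the temperature channel follows the wear schedule
with first-order transitions. The arc is *phased so that the vertical
velocity peaks at each IC*, matching what the wavelet detector reports;
real gait fixes this timing through signal morphology the single
harmonic cannot carry. Two consequences are owned explicitly: (i) the
band-limited norm peaks 3T/4 after each IC, so ground truth carries both
IC times and analytic norm-peak times, and step-peak accuracy is judged
against the latter; (ii) a green event-detection test establishes that
the detector finds periodic gait structure at the stated SNRs, not that
it reproduces a validated algorithm's behaviour on real multi-harmonic,
turning-rich, activity-contaminated signals.

`synthesize_week()` compresses days (default **30 min**) because a real
7 × 24 h × 100 Hz recording (~60M samples per axis) has no place in a
test suite; bout durations follow the four duration categories with
probabilities (0.63, 0.25, 0.08, 0.04) — most bouts at or under 10 s,
the dominant qualitative feature of free-living walking in older
adults — cadence ~N(100, 10) clipped to [60, 140] steps/min, step length
~N(0.60, 0.07) m clipped to [0.30, 0.85], ~30% of worn time walking, and
one day with a long off-body block that fails the proportional valid-day
rule.

`synthesize_cohort()` draws ages from a shifted exponential (mean excess
7.4 years, truncated at 105 — right-skewed like the study population),
SPPB from a logistic-in-age mean curve with rounding and clamping to
0–12, and each metric from the generative gamma model. Default metric
parameters are fixed package choices at cohort-plausible levels (≈6500
steps/day, fast speed ≈1.15 m/s, fast cadence ≈106 steps/min at age 70,
dispersions between 0.005 for cadence and 0.8 for maximum bout
distance), with men shifted up for steps/speed/distance and slightly
down for cadence. They are a *stated world* for testing recovery, not
estimates of the study's unpublished coefficients.

## 6. Numerical choices and degenerate inputs

- All convolutions are zero-phase with reflected-edge padding, FFT-based.
- Resampling interpolates linearly per axis (cubic splines by config);
  a band-limited 2 Hz signal resampled 50→100 Hz stays within 0.01 g of
  the analytic signal.
- Bout assembly is strictly causal; a singleton step never forms a bout.
- Duplicate step times raise a degenerate-bout error rather than a
  division by zero.
- Constant responses fit with β₁ = 0 and a `degenerate` flag; constant
  covariates fall back to an intercept-only fit.
- `exp(η)` is clipped at ±500 inside IRLS to survive wild intermediate
  iterates; the converged optimum is far from the clip.
- Identical-sample Mann-Whitney inputs return p = 1 by construction.

## 7. Known limitations

- **Very slow, short-stepped gait** (cadence ≈ 60 steps/min with ≈0.3 m
  steps) produces vertical accelerations below any usable amplitude
  floor (~0.007 g) and centre-of-mass excursions of ~8 mm for which the
  landing transient alone contaminates the double integral by ~18%;
  norm-based step detection and step-length accuracy degrade there. IC
  detection itself remains accurate across the full tested grid.
- Step-length accuracy is quoted for `h/l ≤ 0.1`; beyond that the
  closed form's sensitivity to `h` grows quickly.
- The wear detector's thresholds are declared defaults; no equivalence
  to the original event-based temperature algorithm is claimed.
- Turning is not segmented, feet are not attributed, and non-walking
  activities are not simulated; a recording containing, e.g., cycling
  would need the upstream activity filter the study device chain
  provides.
- Time-zone handling is a fixed UTC offset; daylight-saving transitions
  within a recording are not modelled.
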