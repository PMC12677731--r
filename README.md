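# freewalk

Free-living gait analysis for older adults from a single lower-back
triaxial accelerometer, plus the cohort statistics that turn per-subject
gait metrics into age- and physical-function trajectories.

## The problem

How much, and how, do older adults actually walk in daily life? A week of
lower-back accelerometry (e.g. 50 Hz, ±8 g, with an on-device temperature
channel) answers this — but only after a long chain of processing: the
sensor must be known to be worn, steps must be found in the signal, steps
must be grouped into walking bouts, each bout needs a cadence, step
length, speed and distance, and the thousands of bouts per person must be
distilled into a handful of interpretable gait outcome metrics. Finally,
cohort questions ("how fast does daily stepping decline with age? with
physical function?") need a regression model matched to the strongly
right-skewed, strictly positive distributions these metrics have.

`freewalk` implements that chain end to end:

1. **Recording I/O** — a documented CSV dialect
   (`t, acc_v, acc_ap, acc_ml[, temp]` + JSON sidecar), resampling
   (50 → 100 Hz by interpolation), temperature-based wear detection, and
   the valid-day rule (≥ 18 h of wear).
2. **Gait events** — initial contacts (ICs) from the vertical
   acceleration via detrending, low-pass filtering, numerical
   integration and a continuous-wavelet (Ricker) transform, taking
   positive peaks between zero-crossings; and candidate step peaks from
   the 3.2 Hz FIR-filtered acceleration norm with adaptive amplitude and
   peak-to-peak thresholds.
3. **Walking bouts** — maximal runs of ≥ 2 steps allowing 1.5 s plus the
   running average step duration between consecutive steps. Per bout:
   duration (first to last IC), cadence `60·(n−1)/duration`, step length
   from the inverted-pendulum model `K · 2·√(2lh − h²)` (vertical
   excursion `h` from doubly integrated vertical acceleration, pendulum
   length `l`, correction factor `K`), speed = cadence/60 × step length,
   distance = duration × speed.
4. **Aggregation** — mean daily steps over valid days; habitual (mode)
   and fast (95th-percentile) cadence and speed over all pooled bouts;
   maximum bout distance; proportions and accumulated minutes in the four
   bout-duration categories (≤10 s, >10–30 s, >30–60 s, >60 s).
5. **Cohort statistics** — age bands (70.0–74.9 … ≥95) and SPPB bands
   (high 10–12, moderate 7–9, low 0–6), Mann-Whitney U, χ² independence,
   descriptive summaries.
6. **Power-law gamma regression** — for gait metric *y* and covariate
   *x* (age − 70, or reversed SPPB 12 − score):

   y = exp(β₀ + β₁ xᵝᵖ) · ε,  ε ~ Gamma(mean 1, variance φ)

   with β_p estimated by profile maximum likelihood and retained only if
   AIC improves over β_p = 1; percent-change predictions
   `100(1 − μ(v₂)/μ(v₁))` between covariate values.
7. **Synthetic data** — recordings with exact ground truth (IC times,
   bout metrics, daily steps, wear schedule) built from the same pendulum
   biomechanics the pipeline inverts, and cohort tables drawn from the
   generative gamma model, so every stage is testable without any study
   data.

## Worked example

```r
library(freewalk)

cfg <- week_config()                     # 7 compressed days, 30 min each
wk  <- synthesize_week(cfg, seed = 1)    # recording + ground truth
res <- run_process(wk$recording, week_run_config(cfg))
print(res$summary, digits = 3)
#>   subject_id daily_steps fast_cadence habitual_cadence fast_speed
#> 1       SYN1         950          117               99       1.27
#>   habitual_speed max_distance prop_le10s prop_gt10_30s prop_gt30_60s prop_gt60s
#> 1          0.975          136      0.592         0.279        0.0796     0.0498
#>   min_le10s min_gt10_30s min_gt30_60s min_gt60s n_valid_days n_bouts
#> 1      11.5         18.7         11.9      16.2            6     201
```

One compressed "week": ~950 steps per valid day, habitual (most frequent)
cadence 99 steps/min and fast (95th-percentile) speed 1.27 m/s, ~59% of
bouts at or under 10 s, and one of seven days invalid (a long non-wear
block).

```r
syn  <- synthesize_cohort(cohort_sim_params(n_female = 300, n_male = 300,
                                            seed = 1))
fits <- run_fit(syn$cohort, "daily_steps", "age")
#> excluding 10 singleton-age subject(s): ...
print(fits$female)
#> <fw_plgamma_fit> n=295  mu = exp(8.7930 -0.01855 * x^1.619), phi=0.2215
#>   loglik=-2605.846  AIC=5219.692  exponent estimated
percent_change(fits$female, 80, 81)
#> [1] 12.07   # predicted % decrease in daily steps from age 80 to 81
```

The cohort was generated with (β₀, β₁, β_p, φ) = (8.78, −0.02, 1.6, 0.25)
for women; the fit recovers (8.79, −0.019, 1.62, 0.22) and AIC keeps the
free exponent — the age decline accelerates, here by ~12% per year at
age 80.

## Command line

```sh
Rscript inst/cli/freewalk.R simulate --seed 1 --out sim/
Rscript inst/cli/freewalk.R process  --in sim/recording.csv --out out/ --day-seconds 1800
Rscript inst/cli/freewalk.R fit      --cohort cohort.csv --metric daily_steps \
                                     --covariate age --out out/
```

`process` writes `bouts.csv`, `days.csv`, `summary.csv` and a
`manifest.json` (config hash, seed, package version; no timestamps, so
identical runs are byte-identical).

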