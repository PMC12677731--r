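test_that("empty protocol yields gravity plus noise and no events", {
  proto <- gait_protocol(data.frame(start = numeric(0), n_steps = integer(0),
                                    cadence = numeric(0),
                                    step_length = numeric(0)),
                         duration = 30, noise_sd = 0)
  syn <- synthesize_recording(proto, rate = 100)
  expect_true(all(syn$recording$acc_v == 1))
  expect_length(syn$truth$ic_times, 0)
  expect_null(syn$truth$bouts)
})

test_that("ground-truth ICs follow the protocol exactly", {
  proto <- gait_protocol(data.frame(start = 5, n_steps = 20, cadence = 120,
                                    step_length = 0.6), duration = 20)
  syn <- synthesize_recording(proto, rate = 100)
  expect_length(syn$truth$ic_times, 20)
  expect_equal(diff(syn$truth$ic_times), rep(0.5, 19))
  tb <- syn$truth$bouts
  expect_equal(tb$duration, 9.5)
  expect_equal(tb$speed, 120 / 60 * 0.6)
  expect_equal(tb$distance, 9.5 * 1.2)
})

test_that("unreachable step lengths are rejected", {
  proto <- gait_protocol(data.frame(start = 5, n_steps = 10, cadence = 100,
                                    step_length = 1.9), duration = 20)
  expect_error(synthesize_recording(proto, rate = 100,
                                    pendulum = pendulum_params(l = 0.7)),
               "unreachable")
})

test_that("generator output is bit-identical under a fixed seed", {
  proto <- gait_protocol(data.frame(start = 5, n_steps = 10, cadence = 100,
                                    step_length = 0.6),
                         duration = 15, noise_sd = 0.05, seed = 7L)
  a <- synthesize_recording(proto, rate = 100)
  b <- synthesize_recording(proto, rate = 100)
  expect_identical(a$recording$acc_v, b$recording$acc_v)
  expect_identical(a$truth, b$truth)
  wa <- synthesize_week(week_config(n_days = 2, day_seconds = 600), seed = 4)
  wb <- synthesize_week(week_config(n_days = 2, day_seconds = 600), seed = 4)
  expect_identical(wa$recording$acc_v, wb$recording$acc_v)
  expect_identical(wa$truth$daily_steps, wb$truth$daily_steps)
})

test_that("pendulum inversion is self-consistent on noise-free signals", {
  # full pipeline example: cadence 100, step length 0.6, l = 0.9, K = 1.25
  proto <- gait_protocol(data.frame(start = 5, n_steps = 25, cadence = 100,
                                    step_length = 0.6), duration = 25)
  syn <- synthesize_recording(proto, rate = 100)
  ics <- detect_initial_contacts(syn$recording$acc_v, 100)
  grp <- assemble_bouts(ics)
  tm <- compute_bout_timing(grp[[1]])
  expect_lt(abs(tm$cadence - 100) / 100, 0.03)
  sl <- estimate_step_lengths(syn$recording$acc_v, 100, grp[[1]])
  expect_lt(abs(mean(sl) - 0.6) / 0.6, 0.10)
  # across step lengths with h/l <= 0.1 (true ICs, no detection error)
  for (target in c(0.4, 0.55, 0.7)) {
    p <- gait_protocol(data.frame(start = 5, n_steps = 20, cadence = 110,
                                  step_length = target), duration = 20)
    s <- synthesize_recording(p, rate = 100)
    est <- mean(estimate_step_lengths(s$recording$acc_v, 100,
                                      s$truth$ic_times))
    expect_lt(abs(est - target) / target, 0.10)
  }
})

test_that("temperature channel tracks the wear schedule", {
  proto <- gait_protocol(data.frame(start = numeric(0), n_steps = integer(0),
                                    cadence = numeric(0),
                                    step_length = numeric(0)),
                         duration = 4000,
                         wear = data.frame(start = c(0, 2000),
                                           end = c(2000, 4000),
                                           worn = c(TRUE, FALSE)))
  syn <- synthesize_recording(proto, rate = 10, temp_tau = 60)
  temp <- syn$recording$temperature
  expect_gt(mean(temp[1000:1900]), 30) # settled worn
  expect_lt(mean(temp[3500:3900]), 23) # settled ambient
})

test_that("cohort generator honours the gamma error model", {
  # vanishing dispersion: responses sit on the model mean
  p <- cohort_sim_params(n_female = 200, n_male = 0,
                         metrics = list(m = list(beta0 = 5, beta1 = -0.03,
                                                 beta_p = 1.5, phi = 1e-6)),
                         male_shift = c(m = 0), seed = 2)
  syn <- synthesize_cohort(p)
  mu <- exp(5 - 0.03 * (syn$cohort$age - 70)^1.5)
  expect_true(all(abs(syn$cohort$m / mu - 1) < 0.01))

  # unit-mean error and variance phi at large n
  p2 <- cohort_sim_params(n_female = 50000, n_male = 0,
                          metrics = list(m = list(beta0 = 5, beta1 = -0.03,
                                                  beta_p = 1.5, phi = 0.25)),
                          male_shift = c(m = 0), seed = 3)
  syn2 <- synthesize_cohort(p2)
  ratio <- syn2$cohort$m / exp(5 - 0.03 * (syn2$cohort$age - 70)^1.5)
  expect_lt(abs(mean(ratio) - 1), 0.01)
  expect_lt(abs(var(ratio) - 0.25) / 0.25, 0.05)

  # null slope: no association between age and the metric
  p3 <- cohort_sim_params(n_female = 4000, n_male = 0,
                          metrics = list(m = list(beta0 = 5, beta1 = 0,
                                                  beta_p = 1, phi = 0.1)),
                          male_shift = c(m = 0), seed = 4)
  syn3 <- synthesize_cohort(p3)
  expect_lt(abs(cor(syn3$cohort$age, syn3$cohort$m, method = "spearman")),
            0.05)
})

test_that("cohort covariates look like the intended population", {
  syn <- synthesize_cohort(cohort_sim_params(n_female = 2000, n_male = 2000,
                                             seed = 9))
  co <- syn$cohort
  expect_true(all(co$age >= 70 & co$age <= 105))
  expect_true(all(co$sppb >= 0 & co$sppb <= 12))
  expect_lt(abs(mean(co$age) - 77.4), 1.5) # right-skewed around ~77
  expect_lt(cor(co$age, co$sppb), -0.3)    # SPPB declines with age
  expect_true(all(co$daily_steps > 0))
})

test_that("a week forced to short bouts lands fully in category 1", {
  cfg <- week_config(n_days = 2, day_seconds = 900,
                     cat_probs = c(1, 0, 0, 0))
  wk <- synthesize_week(cfg, seed = 6)
  cats <- duration_category_summary(wk$truth$bouts)
  expect_equal(unname(cats$proportions[1]), 1)
})
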