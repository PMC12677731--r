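make_bouts <- function(durations, day_index = 1L, cadence = 100,
                       speed = 1.0) {
  n <- length(durations)
  data.frame(start = cumsum(durations + 30) - durations,
             end = cumsum(durations + 30),
             duration = durations,
             n_steps = pmax(2L, round(durations * cadence / 60) + 1L),
             cadence = rep_len(cadence, n),
             mean_step_length = rep_len(speed * 60 / cadence, n),
             speed = rep_len(speed, n),
             distance = durations * rep_len(speed, n),
             day_index = rep_len(as.integer(day_index), n))
}

test_that("mean daily steps averages over valid days only", {
  days <- data.frame(date = as.Date("2023-05-01") + 0:2, day_index = 1:3,
                     wear_hours = c(24, 20, 10),
                     is_valid = c(TRUE, TRUE, FALSE))
  bouts <- rbind(make_bouts(rep(10, 10), 1), make_bouts(rep(10, 10), 2),
                 make_bouts(rep(10, 50), 3))
  b1 <- sum(bouts$n_steps[bouts$day_index == 1])
  b2 <- sum(bouts$n_steps[bouts$day_index == 2])
  expect_equal(mean_daily_steps(bouts, days), (b1 + b2) / 2)
  # a valid day without bouts drags the mean down
  days2 <- rbind(days, data.frame(date = as.Date("2023-05-04"),
                                  day_index = 4, wear_hours = 24,
                                  is_valid = TRUE))
  expect_equal(mean_daily_steps(bouts, days2), (b1 + b2 + 0) / 3)
  # no valid day: missing, not zero
  days$is_valid <- FALSE
  expect_true(is.na(mean_daily_steps(bouts, days)))
})

test_that("percentile95 interpolates between order statistics", {
  expect_equal(percentile95(1:100), 95.05)
  expect_equal(percentile95(rep(3.2, 10)), 3.2)
  expect_equal(percentile95(7), 7)
  expect_true(is.na(percentile95(numeric(0))))
  # agrees with the sort-based base definition (type 7) on random data
  set.seed(31)
  for (i in 1:20) {
    v <- rnorm(sample(5:200, 1))
    expect_equal(percentile95(v),
                 unname(quantile(v, 0.95, type = 7)))
  }
})

test_that("histogram mode uses zero-anchored bins with low-bin ties", {
  expect_equal(mode_estimate(c(1.0, 1.0, 2.0), 1), 1.5)
  expect_equal(mode_estimate(rep(4.2, 5), 0.05), 4.225)
  expect_true(is.na(mode_estimate(numeric(0), 1)))
  # ties broken toward the lower bin
  expect_equal(mode_estimate(c(0.5, 1.5), 1), 0.5)
  # large unimodal sample: estimate within one bin of the true mode
  set.seed(99)
  v <- rgamma(10000, shape = 25, scale = 4) # mode at (25-1)*4 = 96
  expect_lt(abs(mode_estimate(v, 2) - 96), 4)
})

test_that("duration categories bin with closed-left boundaries", {
  b <- make_bouts(c(5, 15, 45, 90))
  cats <- duration_category_summary(b)
  expect_equal(unname(cats$proportions), rep(0.25, 4))
  expect_equal(unname(cats$minutes), c(5, 15, 45, 90) / 60)
  # boundary cases belong to the shorter category
  bb <- make_bouts(c(10, 30, 60))
  cc <- duration_category_summary(bb)
  expect_equal(unname(cc$proportions), c(1/3, 1/3, 1/3, 0))
  # empty: proportions missing, minutes zero
  e <- duration_category_summary(make_bouts(numeric(0)))
  expect_true(all(is.na(e$proportions)))
  expect_equal(unname(e$minutes), rep(0, 4))
})

test_that("max bout distance", {
  b <- make_bouts(c(3, 60, 12)) # distances equal durations at speed 1
  expect_equal(max_bout_distance(b), 60)
  expect_equal(max_bout_distance(make_bouts(42)), 42)
  expect_true(is.na(max_bout_distance(make_bouts(numeric(0)))))
})

test_that("subject summary: conservation, edge cases, order invariance", {
  days <- data.frame(date = as.Date("2023-05-01") + 0:1, day_index = 1:2,
                     wear_hours = c(24, 24), is_valid = c(TRUE, TRUE))
  set.seed(17)
  b <- make_bouts(runif(40, 2, 120), day_index = sample(1:2, 40, TRUE))
  s <- build_subject_summary(b, days)
  mins <- c(s$min_le10s, s$min_gt10_30s, s$min_gt30_60s, s$min_gt60s)
  expect_equal(sum(mins), sum(b$duration) / 60) # exact conservation
  props <- c(s$prop_le10s, s$prop_gt10_30s, s$prop_gt30_60s, s$prop_gt60s)
  expect_equal(sum(props), 1)
  # order invariance of weekly metrics
  s2 <- build_subject_summary(b[sample(nrow(b)), ], days)
  expect_equal(s2, s)
  # empty bout table: all missing, n_bouts 0
  s0 <- build_subject_summary(make_bouts(numeric(0)), days)
  expect_true(is.na(s0$fast_cadence) && is.na(s0$habitual_speed) &&
                is.na(s0$max_distance))
  expect_equal(s0$n_bouts, 0)
  expect_equal(s0$daily_steps, 0) # valid days exist, no walking
  # single bout: fast = habitual-bin behaviour, both from that bout
  s1 <- build_subject_summary(make_bouts(20), days)
  expect_equal(s1$fast_cadence, 100)
  expect_equal(s1$habitual_cadence, 101) # midpoint of bin [100, 102)
  expect_equal(s1$fast_speed, 1.0)
})

test_that("invalid-day bouts affect only the daily step metric", {
  days <- data.frame(date = as.Date("2023-05-01") + 0:1, day_index = 1:2,
                     wear_hours = c(24, 6), is_valid = c(TRUE, FALSE))
  b <- rbind(make_bouts(c(20, 40), 1), make_bouts(c(100, 15), 2))
  s_all <- build_subject_summary(b, days)
  s_cut <- build_subject_summary(b[b$day_index == 1, ], days)
  expect_equal(s_all$daily_steps, s_cut$daily_steps)
  expect_false(isTRUE(all.equal(s_all$max_distance, s_cut$max_distance)))
})
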