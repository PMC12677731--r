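test_that("covariate transforms shift to the reference", {
  expect_equal(transform_covariate(70, "age"), 0)
  expect_equal(transform_covariate(c(75.5, 103), "age"), c(5.5, 33))
  expect_warning(x <- transform_covariate(65, "age"), "clamped")
  expect_equal(x, 0)
  expect_equal(transform_covariate(12, "sppb"), 0)
  expect_equal(transform_covariate(0, "sppb"), 12)
  expect_error(transform_covariate(13, "sppb"))
})

test_that("gamma log-likelihood matches the closed form term by term", {
  set.seed(12)
  x <- c(0, 1.5, 4, 9, 20)
  y <- c(5000, 4800, 4000, 2500, 900)
  b0 <- 8.6; b1 <- -0.03; bp <- 1.3; phi <- 0.2
  mu <- exp(b0 + b1 * x^bp)
  expect_equal(gamma_loglik(b0, b1, bp, phi, x, y),
               sum(gamma_logdens_direct(y, mu, phi)), tolerance = 1e-10)
  # x = 0: value independent of beta1
  expect_equal(gamma_loglik(b0, 5, bp, phi, 0, 100),
               gamma_loglik(b0, -5, bp, phi, 0, 100))
  # density at the mean decreases as dispersion grows
  lls <- vapply(c(0.05, 0.2, 0.8), function(p)
    gamma_loglik(log(100), 0, 1, p, 0, 100), numeric(1))
  expect_true(all(diff(lls) < 0))
  expect_error(gamma_loglik(b0, b1, bp, phi, 1, -2), "positive")
})

test_that("fixed-exponent fit reproduces the reference gamma GLM", {
  set.seed(41)
  for (i in 1:3) {
    n <- 200
    x <- runif(n, 0, 25)
    y <- exp(8 - 0.04 * x) * rgamma(n, shape = 5, scale = 0.2)
    f <- fit_powerlaw_gamma(x, y, fix_exponent = TRUE)
    g <- stats::glm(y ~ x, family = Gamma(link = "log"))
    expect_equal(f$beta0, unname(coef(g)[1]), tolerance = 1e-5)
    expect_equal(f$beta1, unname(coef(g)[2]), tolerance = 1e-5)
    expect_equal(f$beta_p, 1)
    expect_true(f$exponent_fixed)
    expect_equal(f$aic, 2 * 3 - 2 * f$loglik)
  }
})

test_that("free-exponent fit recovers generating parameters", {
  set.seed(1234)
  n <- 500
  x <- runif(n, 0, 30)
  y <- exp(8.7 - 0.02 * x^1.6) * rgamma(n, shape = 4, scale = 0.25)
  f <- fit_powerlaw_gamma(x, y)
  expect_lt(abs(f$beta1 - (-0.02)), 3 * f$se_beta1)
  expect_lt(abs(f$beta_p - 1.6), 0.25)
  expect_lt(abs(f$phi - 0.25), 0.05)
  expect_equal(f$aic, 2 * 4 - 2 * f$loglik)
  # nesting: the free fit cannot be beaten by the fixed-exponent one,
  # and the reported loglik is the likelihood at the reported parameters
  fixed <- fit_powerlaw_gamma(x, y, fix_exponent = TRUE)
  expect_gte(f$loglik, fixed$loglik - 1e-6)
  expect_equal(f$loglik,
               gamma_loglik(f$beta0, f$beta1, f$beta_p, f$phi, x, y),
               tolerance = 1e-8)
})

test_that("null slope: beta1 near zero and AIC prefers the fixed model", {
  set.seed(55)
  n <- 500
  x <- runif(n, 0, 30)
  y <- exp(7.5) * rgamma(n, shape = 4, scale = 0.25)
  free <- fit_powerlaw_gamma(x, y)
  fixed <- fit_powerlaw_gamma(x, y, fix_exponent = TRUE)
  expect_lt(abs(fixed$beta1), 0.01)
  expect_true(select_exponent_model(free, fixed)$exponent_fixed)
})

test_that("constant response is flagged degenerate", {
  x <- runif(20, 0, 10)
  y <- rep(250, 20)
  f <- fit_powerlaw_gamma(x, y, fix_exponent = TRUE)
  expect_true(f$degenerate)
  expect_lt(abs(f$beta1), 1e-8)
})

test_that("exponent-model selection applies the strict-improvement rule", {
  base <- structure(list(beta0 = 8, beta1 = -0.02, beta_p = 1.5, phi = 0.2,
                         loglik = -50, aic = 108, n = 100,
                         exponent_fixed = FALSE, covariate_kind = "age"),
                    class = "fw_plgamma_fit")
  fixed <- base
  fixed$exponent_fixed <- TRUE
  fixed$beta_p <- 1
  fixed$loglik <- -51
  fixed$aic <- 108
  expect_true(select_exponent_model(base, fixed)$exponent_fixed) # tie
  better <- base; better$aic <- 107
  expect_false(select_exponent_model(better, fixed)$exponent_fixed)
  other_n <- fixed; other_n$n <- 99
  expect_error(select_exponent_model(base, other_n), "same data")
  bad <- base; bad$loglik <- -60
  expect_error(select_exponent_model(bad, fixed), "inconsistency")
})

test_that("percent change follows the closed form", {
  f <- structure(list(beta0 = 8, beta1 = 0, beta_p = 1,
                      covariate_kind = "age"), class = "fw_plgamma_fit")
  expect_equal(percent_change(f, 70, 90), 0)
  f$beta1 <- -0.05
  expect_equal(percent_change(f, 75, 76), 100 * (1 - exp(-0.05)),
               tolerance = 1e-10) # 4.877%
  # invariance to the intercept
  f2 <- f; f2$beta0 <- -3
  expect_equal(percent_change(f2, 75, 76), percent_change(f, 75, 76))
  # accelerating decline for beta_p = 2
  f3 <- structure(list(beta0 = 8, beta1 = -0.001, beta_p = 2,
                       covariate_kind = "age"), class = "fw_plgamma_fit")
  expect_gt(percent_change(f3, 90, 91), percent_change(f3, 70, 71))
  # sppb covariate: reversal handled inside
  f4 <- structure(list(beta0 = 8, beta1 = -0.05, beta_p = 1,
                       covariate_kind = "sppb"), class = "fw_plgamma_fit")
  expect_equal(percent_change(f4, 12, 11), 100 * (1 - exp(-0.05)))
})

test_that("singleton integer ages are excluded per sex", {
  co <- data.frame(sex = c("f", "f", "f", "m", "m"),
                   age = c(75.2, 75.8, 100.1, 75.5, 80.0))
  suppressMessages(out <- exclude_singleton_ages(co))
  expect_equal(nrow(out), 2) # both 75-year-old women retained
  expect_true(all(floor(out$age) == 75 & out$sex == "f"))
  expect_equal(nrow(exclude_singleton_ages(co[0, ])), 0)
})
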