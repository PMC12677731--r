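#' Shift a covariate to its reference
#'
#' Age enters the regression as `age - 70` (the cohort's youngest age) and
#' the SPPB score is reversed as `12 - score` so the maximum score is the
#' reference; both transformed covariates are non-negative.
#'
#' @param value ages in years or SPPB scores.
#' @param kind `"age"` or `"sppb"`.
#' @return transformed covariate `x >= 0`.
#' @export
transform_covariate <- function(value, kind = c("age", "sppb")) {
  kind <- match.arg(kind)
  if (kind == "age") {
    if (any(value < 70)) warning("age below 70 clamped to the reference")
    pmax(0, value - 70)
  } else {
    stopifnot(all(value >= 0 & value <= 12))
    12 - value
  }
}

#' Log-likelihood of the power-law gamma model
#'
#' The response is modelled as `y = exp(beta0 + beta1 * x^beta_p) * eps`
#' with `eps` gamma-distributed with mean 1 and variance `phi`, i.e.
#' `y ~ Gamma(shape = 1/phi, scale = phi * mu)` with
#' `mu = exp(beta0 + beta1 * x^beta_p)`.
#'
#' @param beta0,beta1,beta_p,phi model parameters (`phi > 0`, `beta_p > 0`).
#' @param x non-negative transformed covariates.
#' @param y strictly positive responses.
#' @return the summed log-likelihood.
#' @export
gamma_loglik <- function(beta0, beta1, beta_p, phi, x, y) {
  if (any(y <= 0)) stop("responses must be strictly positive")
  stopifnot(phi > 0, beta_p > 0, length(x) == length(y))
  mu <- exp(beta0 + beta1 * x^beta_p)
  sum(dgamma(y, shape = 1 / phi, scale = phi * mu, log = TRUE))
}

#' Fitting configuration for the power-law gamma model
#'
#' @param exponent_grid candidate exponents for the profile-likelihood scan.
#' @param refine_tol tolerance of the golden-section refinement of `beta_p`
#'   and of the IRLS convergence check.
#' @param max_iter IRLS iteration cap.
#' @param se_method `"full"` (expected information including the exponent
#'   column, so the slope's SE reflects the beta1-beta_p ridge; the default)
#'   or `"fixed_exponent"` (`beta_p` held at its estimate).
#' @return list of class `fw_fit_config`.
#' @export
fit_config <- function(exponent_grid = seq(0.1, 4, by = 0.05),
                       refine_tol = 1e-6, max_iter = 100,
                       se_method = c("full", "fixed_exponent")) {
  stopifnot(all(exponent_grid > 0), refine_tol > 0, max_iter >= 1)
  structure(list(exponent_grid = exponent_grid, refine_tol = refine_tol,
                 max_iter = max_iter, se_method = match.arg(se_method)),
            class = "fw_fit_config")
}

# IRLS for a log-link gamma GLM with design [1, z]; the coefficient MLE is
# free of phi.  Returns beta and convergence flag.
gamma_irls <- function(z, y, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, z)
  if (qr(X)$rank < 2L) { # constant covariate: intercept-only fit
    return(list(beta = c(log(mean(y)), 0), converged = TRUE,
                degenerate = TRUE))
  }
  beta <- stats::lm.fit(X, log(y))$coefficients
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -500), 500)
    mu <- exp(eta)
    zw <- eta + (y - mu) / mu # working response; weights are all 1
    beta_new <- stats::lm.fit(X, zw)$coefficients
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      return(list(beta = beta_new, converged = TRUE, degenerate = FALSE))
    }
    beta <- beta_new
  }
  list(beta = beta, converged = FALSE, degenerate = FALSE)
}

# ML estimate of the dispersion phi given fitted means: solves
# log(a) - digamma(a) = mean(r - log r) - 1 for the shape a = 1/phi,
# where r = y / mu.
phi_mle <- function(y, mu) {
  r <- y / mu
  cc <- mean(r - log(r)) - 1
  if (cc <= 1e-12) return(1e-8) # essentially perfect fit
  f <- function(la) { a <- exp(la); log(a) - digamma(a) - cc }
  sol <- uniroot(f, lower = log(1e-8), upper = log(1e10), tol = 1e-12)
  1 / exp(sol$root)
}

# Profile log-likelihood in beta_p: beta by IRLS, phi by its ML equation.
profile_fit <- function(x, y, beta_p, max_iter = 100) {
  ir <- gamma_irls(x^beta_p, y, max_iter = max_iter)
  mu <- exp(pmin(pmax(ir$beta[1] + ir$beta[2] * x^beta_p, -500), 500))
  phi <- phi_mle(y, mu)
  ll <- sum(dgamma(y, shape = 1 / phi, scale = phi * mu, log = TRUE))
  list(beta = ir$beta, phi = phi, loglik = ll, converged = ir$converged,
       degenerate = ir$degenerate)
}

#' Fit the power-law gamma regression
#'
#' Maximum-likelihood fit of `y = exp(beta0 + beta1 * x^beta_p) * eps`,
#' `eps ~ Gamma(mean 1, variance phi)`.  With `fix_exponent = TRUE` the
#' exponent is held at 1 (a standard log-link gamma GLM); otherwise
#' `beta_p` is profiled over `config$exponent_grid` and refined by
#' golden-section search.  The dispersion is estimated by ML jointly with
#' the coefficients at every candidate exponent so AIC comparisons between
#' the fixed and free models are coherent.
#'
#' @param x non-negative transformed covariates (see
#'   [transform_covariate()]); `n >= 10`.
#' @param y strictly positive responses.
#' @param fix_exponent hold `beta_p = 1`?
#' @param config see [fit_config()].
#' @param covariate_kind `"age"` or `"sppb"`, recorded for prediction.
#' @return An object of class `fw_plgamma_fit`: `beta0`, `beta1`, `beta_p`,
#'   `phi`, `loglik`, `aic` (`2k - 2 loglik`, `k = 3` fixed / `4` free),
#'   `n`, `exponent_fixed`, `se_beta0`, `se_beta1`, `degenerate`,
#'   `covariate_kind`.
#' @export
fit_powerlaw_gamma <- function(x, y, fix_exponent = FALSE,
                               config = fit_config(),
                               covariate_kind = "age") {
  stopifnot(length(x) == length(y), length(y) >= 10, all(x >= 0))
  if (any(y <= 0)) stop("responses must be strictly positive")
  n <- length(y)
  if (fix_exponent) {
    pf <- profile_fit(x, y, 1, config$max_iter)
    beta_p <- 1
  } else {
    lls <- vapply(config$exponent_grid,
                  function(bp) profile_fit(x, y, bp, config$max_iter)$loglik,
                  numeric(1))
    k <- which.max(lls)
    lo <- config$exponent_grid[max(1L, k - 1L)]
    hi <- config$exponent_grid[min(length(lls), k + 1L)]
    opt <- stats::optimize(function(bp) profile_fit(x, y, bp,
                                                    config$max_iter)$loglik,
                           interval = c(lo, hi), maximum = TRUE,
                           tol = config$refine_tol)
    beta_p <- opt$maximum
    pf <- profile_fit(x, y, beta_p, config$max_iter)
    if (pf$degenerate) beta_p <- 1 # constant response: exponent meaningless
  }
  if (stats::var(y) == 0) { # constant response: slope is meaningless
    pf$degenerate <- TRUE
    beta_p <- 1
  }
  if (!pf$converged)
    stop("IRLS did not converge; best iterate: beta0=", pf$beta[1],
         " beta1=", pf$beta[2], " beta_p=", beta_p)
  k_par <- 3 + as.integer(!fix_exponent)
  se <- fit_standard_errors(x, y, pf$beta, beta_p, pf$phi,
                            fix_exponent || pf$degenerate, config$se_method)
  structure(list(beta0 = unname(pf$beta[1]), beta1 = unname(pf$beta[2]),
                 beta_p = beta_p, phi = pf$phi, loglik = pf$loglik,
                 aic = 2 * k_par - 2 * pf$loglik, n = n,
                 exponent_fixed = fix_exponent,
                 se_beta0 = se[1], se_beta1 = se[2],
                 degenerate = pf$degenerate,
                 covariate_kind = covariate_kind),
            class = "fw_plgamma_fit")
}

# Standard errors for (beta0, beta1) from the expected (Fisher) information
# at the optimum.  The information is block-diagonal between the linear
# predictor's parameters and phi, and for the predictor parameters theta it
# is (1/phi) * G'G with G_i = d eta_i / d theta.  "full" includes the
# exponent column (beta1 * x^beta_p * log x), so the strong beta1-beta_p
# ridge widens the slope's SE; "fixed_exponent" drops it.
fit_standard_errors <- function(x, y, beta, beta_p, phi, exponent_fixed,
                                se_method) {
  u <- x^beta_p
  G <- cbind(1, u)
  if (!exponent_fixed && se_method == "full") {
    dcol <- beta[2] * u * ifelse(x > 0, log(x), 0)
    if (any(dcol != 0)) G <- cbind(G, dcol)
  }
  V <- tryCatch(phi * solve(crossprod(G)), error = function(e) NULL)
  if (is.null(V) && ncol(G) == 3L) # ridge collapsed: drop the exponent col
    V <- tryCatch(phi * solve(crossprod(G[, 1:2])), error = function(e) NULL)
  if (is.null(V)) return(c(NA_real_, NA_real_))
  sqrt(pmax(0, diag(V)[1:2]))
}

#' @export
print.fw_plgamma_fit <- function(x, ...) {
  cat(sprintf(
    "<fw_plgamma_fit> n=%d  mu = exp(%.4f %+.5f * x^%.3f), phi=%.4f\n",
    x$n, x$beta0, x$beta1, x$beta_p, x$phi))
  cat(sprintf("  loglik=%.3f  AIC=%.3f  exponent %s%s\n", x$loglik, x$aic,
              if (x$exponent_fixed) "fixed at 1" else "estimated",
              if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  invisible(x)
}

#' Choose between the free- and fixed-exponent models by AIC
#'
#' The free-exponent model is retained only when its AIC strictly improves
#' on the fixed-exponent (`beta_p = 1`) model; ties keep the simpler model.
#'
#' @param fit_free fit with estimated exponent.
#' @param fit_fixed fit with `beta_p = 1`.
#' @return the selected `fw_plgamma_fit`.
#' @export
select_exponent_model <- function(fit_free, fit_fixed) {
  if (fit_free$n != fit_fixed$n)
    stop("fits were not computed on the same data (different n)")
  if (fit_free$loglik < fit_fixed$loglik - 1e-6)
    stop("internal inconsistency: free-exponent log-likelihood below the ",
         "nested fixed-exponent model")
  if (fit_free$aic < fit_fixed$aic) fit_free else fit_fixed
}

#' Predicted percent change of a gait metric between two covariate values
#'
#' `100 * (1 - mu(v_to) / mu(v_from))` from the fitted model; positive
#' values are decreases.  Covariate values are on the original scale (years
#' of age, or SPPB points).
#'
#' @param fit an `fw_plgamma_fit`.
#' @param v_from,v_to covariate values on the original scale.
#' @return percent change (positive = decrease).
#' @export
percent_change <- function(fit, v_from, v_to) {
  x <- transform_covariate(c(v_from, v_to), fit$covariate_kind)
  eta <- fit$beta0 + fit$beta1 * x^fit$beta_p
  100 * (1 - exp(eta[2] - eta[1]))
}

#' Drop single representatives of an integer age within each sex
#'
#' Subjects who are the only representative of their (sex, integer age)
#' cell are excluded before regression to prevent disproportionate
#' influence of extreme ages.
#'
#' @param cohort data.frame with `sex` and `age` columns.
#' @return the cohort without singleton-age rows; the removed subjects are
#'   reported via `message()`.
#' @export
exclude_singleton_ages <- function(cohort) {
  if (!nrow(cohort)) return(cohort)
  key <- paste(cohort$sex, floor(cohort$age))
  counts <- table(key)
  drop <- key %in% names(counts)[counts == 1L]
  if (any(drop))
    message("excluding ", sum(drop), " singleton-age subject(s): ",
            paste(unique(key[drop]), collapse = ", "))
  cohort[!drop, , drop = FALSE]
}
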