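#' Assign age band and physical-function band
#'
#' Ages are banded in 5-year groups from 70 (70.0-74.9 ... 90.0-94.9, >=95);
#' the Short Physical Performance Battery (SPPB, 0-12) is banded as high
#' (10-12), moderate (7-9) and low (0-6).
#'
#' @param age age in years (>= 70 for the study population; younger ages are
#'   labelled `"<70"` with a warning).
#' @param sppb integer SPPB total score, 0-12.
#' @return data.frame with character columns `age_band` and `sppb_band`.
#' @export
assign_groups <- function(age, sppb) {
  stopifnot(length(age) == length(sppb), all(sppb >= 0 & sppb <= 12))
  if (any(age < 70)) warning("age below 70: labelled '<70'")
  breaks <- c(70, 75, 80, 85, 90, 95)
  labs <- c("70.0-74.9", "75.0-79.9", "80.0-84.9", "85.0-89.9",
            "90.0-94.9", ">=95.0")
  ab <- ifelse(age < 70, "<70", labs[findInterval(age, breaks)])
  sb <- ifelse(sppb >= 10, "high", ifelse(sppb >= 7, "moderate", "low"))
  data.frame(age_band = ab, sppb_band = sb)
}

#' Mann-Whitney U test
#'
#' Rank-sum test of stochastic equality of two samples.  For small samples
#' (`min(n) <= exact_max` and no ties) the exact two-sided p-value is
#' computed from the null distribution of U; otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest `min(n_x, n_y)` for which the exact p is used.
#' @return list with `U` (statistic for `x`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1L) return(list(U = U, p = 1))
  if (min(nx, ny) <= exact_max && !ties) {
    # exact null distribution of U (no ties): pwilcox enumerates it
    p_le <- pwilcox(U, nx, ny)
    p_ge <- 1 - pwilcox(U - 1, nx, ny)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    n <- nx + ny
    sig2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    # Without ties an Edgeworth kurtosis term sharpens the tail areas
    # (the null U distribution is symmetric but platykurtic, excess
    # kurtosis -6(nx^2+ny^2+nx*ny+nx+ny)/(5*nx*ny*(n+1))); with ties the
    # plain continuity-corrected normal is used.
    g2 <- if (ties) 0 else
      -6 * (nx^2 + ny^2 + nx * ny + nx + ny) / (5 * nx * ny * (n + 1))
    Fz <- function(z) pnorm(z) - dnorm(z) * (g2 / 24) * (z^3 - 3 * z)
    p_le <- Fz((U + 0.5 - mu) / sqrt(sig2))
    p_ge <- 1 - Fz((U - 0.5 - mu) / sqrt(sig2))
    p <- min(1, 2 * min(p_le, p_ge))
  }
  list(U = U, p = p)
}

#' Chi-squared test of independence
#'
#' Pearson's statistic `sum((O - E)^2 / E)` with expected counts from the
#' margins, no continuity correction, `df = (r - 1)(c - 1)`.
#'
#' @param table matrix of non-negative counts.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi2_independence <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), sum(table) > 0, nrow(table) >= 2,
            ncol(table) >= 2)
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: a row or column margin is zero")
  E <- outer(rs, cs) / sum(table)
  chi2 <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Descriptive statistics of a sample
#'
#' @param values non-empty numeric sample.
#' @return list with `median`, `p25`, `p75` (linear interpolation), `mean`,
#'   `sd`.
#' @export
describe <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) > 0)
  list(median = median(values), p25 = percentile95(values, 0.25),
       p75 = percentile95(values, 0.75), mean = mean(values),
       sd = if (length(values) > 1L) sd(values) else 0)
}
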