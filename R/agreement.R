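#' Coefficient of determination of an OLS fit
#'
#' R-squared of ordinary least squares of `y` on `x` with a free intercept.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return R-squared in [0, 1]; `NA` with a warning for constant `x`.
#' @export
linear_r2 <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3) stopf("at least 3 paired observations are required")
  if (stats::sd(x) == 0) {
    warning("R-squared undefined for constant x", call. = FALSE)
    return(NA_real_)
  }
  fit <- stats::lm(y ~ x)
  # computed from the fit residuals; summary.lm() warns on perfect fits
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Percent-scale Bland-Altman method comparison
#'
#' Differences are expressed in percent of the pairwise mean,
#' `d_i = 100 * (m1_i - m2_i) / ((m1_i + m2_i) / 2)`, which puts small and
#' large kidneys on the same scale.  The bias is `mean(d)`, the limits of
#' agreement `bias +/- 1.96 * sd(d)` (sample SD), and the bias confidence
#' interval uses the t distribution,
#' `bias +/- t(0.975, n-1) * sd(d) / sqrt(n)`.  The bias is flagged
#' significant when zero (the line of equality) lies outside that interval.
#'
#' @param m1,m2 paired volume measurements; every pairwise mean must be
#'   positive.
#' @return list of class `agreement_result`: `bias_pct`, `loa_low_pct`,
#'   `loa_high_pct`, `bias_ci_low_pct`, `bias_ci_high_pct`,
#'   `bias_significant`, `n`, and the per-pair differences `d_pct`.
#' @export
bland_altman_percent <- function(m1, m2) {
  if (length(m1) != length(m2)) stopf("m1 and m2 lengths differ")
  n <- length(m1)
  if (n < 2) stopf("at least 2 paired measurements are required")
  mu <- (m1 + m2) / 2
  if (any(mu <= 0)) stopf("pairwise means must be positive on the percent scale")
  d <- 100 * (m1 - m2) / mu
  bias <- mean(d)
  s <- stats::sd(d)
  ci_half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  res <- list(bias_pct = bias,
              loa_low_pct = bias - 1.96 * s,
              loa_high_pct = bias + 1.96 * s,
              bias_ci_low_pct = bias - ci_half,
              bias_ci_high_pct = bias + ci_half,
              bias_significant = (bias - ci_half > 0) | (bias + ci_half < 0),
              n = n, d_pct = d)
  class(res) <- "agreement_result"
  res
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (%% of mean), n = %d\n", x$n))
  cat(sprintf("  bias %.2f%% [CI %.2f, %.2f]%s\n", x$bias_pct,
              x$bias_ci_low_pct, x$bias_ci_high_pct,
              if (x$bias_significant) " (significant)" else ""))
  cat(sprintf("  limits of agreement %.2f%% to %.2f%%\n",
              x$loa_low_pct, x$loa_high_pct))
  invisible(x)
}

#' Full method-comparison summary
#'
#' Combines OLS R-squared and the percent Bland-Altman panel for two paired
#' volume series (e.g. reader vs AI, or US vs MRI).
#'
#' @param m1,m2 paired measurements.
#' @return list with `r2` and the [bland_altman_percent()] result.
#' @export
compare_methods <- function(m1, m2) {
  list(r2 = linear_r2(m1, m2), bland_altman = bland_altman_percent(m1, m2))
}
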