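#' Paired t-test
#'
#' Two-sided paired t-test on matched value pairs: the statistic is
#' `mean(d) / (sd(d) / sqrt(n))` for differences `d = x - y` with the
#' sample (n-1) standard deviation, and the p-value comes from the t
#' distribution with n-1 degrees of freedom, evaluated through the
#' regularized incomplete beta function.
#'
#' @param x,y Paired numeric vectors of equal length n >= 3.
#' @return Object of class `ttest_result`: `t`, `df`, `p`,
#'   `mean_difference`, `n`.
#' @export
paired_t_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_validation("x and y must have equal length")
  if (n < 3) stop_validation("paired t-test needs n >= 3")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) {
    stop_validation("degenerate variance: all paired differences are equal")
  }
  tval <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- stats::pbeta(df / (df + tval^2), df / 2, 0.5)
  structure(
    list(t = tval, df = df, p = p, mean_difference = mean(d), n = n),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Paired t-test: t(%d) = %.4f, p = %.5f, mean diff = %.5g\n",
              x$df, x$t, x$p, x$mean_difference))
  invisible(x)
}

#' Simple linear regression
#'
#' Ordinary least squares of y on x with `R^2 = 1 - SSres/SStot` and a
#' two-sided p-value for the slope from `t = slope / SE(slope)` on n-2
#' degrees of freedom.
#'
#' @param x Predictor values (non-constant, n >= 3).
#' @param y Response values.
#' @return Object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p`, `t`, `n`.
#' @export
linear_regression <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_validation("x and y must have equal length")
  if (n < 3) stop_validation("regression needs n >= 3")
  if (stats::var(x) == 0) stop_validation("constant predictor")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  df <- n - 2
  se <- sqrt(ss_res / df / sxx)
  if (se == 0) {
    tval <- if (slope == 0) 0 else Inf
    p <- if (slope == 0) 1 else 0
  } else {
    tval <- slope / se
    p <- stats::pbeta(df / (df + tval^2), df / 2, 0.5)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         p = p, t = tval, n = n),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "OLS: slope = %.5g, intercept = %.5g, R^2 = %.4f, p = %.5f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$p, x$n))
  invisible(x)
}
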