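#' Student-t quantile
#'
#' Inverse CDF of the Student t distribution, as used by the
#' prediction-interval construction.
#'
#' @param p probability in (0, 1).
#' @param df degrees of freedom, >= 1.
#' @return the `p` quantile.
#' @export
t_quantile <- function(p, df) {
  stopifnot(is.numeric(p), is.numeric(df))
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  if (any(df < 1)) stop("df must be >= 1")
  stats::qt(p, df)
}

#' Two-sided prediction interval for the maximum specific growth rate
#'
#' A new sample's growth rate is predicted to fall in
#' `mean +/- t(1 - (1 - level)/2, n - 1) * s * sqrt(1 + 1/n)`,
#' where `mean`, `s` and `n` are the mean, sample standard deviation and count
#' of the per-sample fitted rates. The `sqrt(1 + 1/n)` factor makes this a
#' prediction interval (for a single future observation) rather than a
#' confidence interval on the mean. Degrees of freedom are `n - 1` with `n`
#' the number of fitted samples.
#'
#' @param est an [aggregate_fits()] result, or a list with `mu_m_mean`
#'   (or `mean`), `s`, `n`.
#' @param level interval level, default 0.95.
#' @return an object of class `prediction_interval`: list with `mean`, `s`,
#'   `n`, `level`, `upper`, `lower`.
#' @export
#' @examples
#' pi95 <- mu_m_prediction_interval(list(mean = 2.76e-2, s = 1.46e-3, n = 18))
#' pi95$upper   # ~3.07e-2 1/h
#' pi95$lower   # ~2.44e-2 1/h
mu_m_prediction_interval <- function(est, level = 0.95) {
  m <- if (!is.null(est$mu_m_mean)) est$mu_m_mean else est$mean
  s <- est$s
  n <- est$n
  stopifnot(is.numeric(m), is.numeric(s), is.numeric(n),
            is.numeric(level), level > 0, level < 1)
  if (is.null(m)) stop("est must supply a mean")
  if (n < 2) stop("n must be >= 2")
  if (s < 0) stop("s must be >= 0")
  half <- t_quantile(1 - (1 - level) / 2, n - 1) * s * sqrt(1 + 1 / n)
  lower <- m - half
  if (lower < 0)
    warning("lower prediction bound is negative (biologically implausible); ",
            "not clipped")
  structure(
    list(mean = m, s = s, n = n, level = level,
         upper = m + half, lower = lower),
    class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf("%.0f%% prediction interval for mu_m (n = %d, s = %.3g):\n",
              100 * x$level, x$n, x$s))
  cat(sprintf("  lower = %.4g 1/h\n  mean  = %.4g 1/h\n  upper = %.4g 1/h\n",
              x$lower, x$mean, x$upper))
  invisible(x)
}
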