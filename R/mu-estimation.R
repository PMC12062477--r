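#' Residual sum of squares between measured and predicted cell counts
#'
#' @param measured measured adhesion-cell counts.
#' @param predicted model-predicted counts of the same length.
#' @return `sum((measured - predicted)^2)`, in cells^2.
#' @export
residual_sum_of_squares <- function(measured, predicted) {
  stopifnot(is.numeric(measured), is.numeric(predicted))
  if (length(measured) != length(predicted))
    stop("measured and predicted must have equal length")
  if (length(measured) < 1L) stop("at least one measurement is required")
  sum((measured - predicted)^2)
}

#' Fit the maximum specific growth rate for one sample
#'
#' Minimizes the residual sum of squares between the sample's measured total
#' counts and the model prediction `N(t) = S * X(t)`, over `mu_m` alone. The
#' other model inputs (`alpha`, `epsilon`, `X_m`) are held fixed - by
#' convention at the means over the fitting dataset (see
#' [fit_experiment()]), so each sample's deviation from the shared
#' curve is absorbed into its fitted rate. A per-sample mode simply passes
#' that sample's own parameters in `fixed`.
#'
#' The optimizer is a derivative-free Nelder-Mead simplex with an iteration
#' cap of 5000 and an objective tolerance of 1e-10. `mu_m` is unconstrained in
#' sign; negative optima are flagged, not clipped. Non-convergence is flagged
#' on the returned fit, never raised.
#'
#' @param obs a [tiled_observation()].
#' @param fixed list or one-row data.frame with `alpha`, `epsilon`, `X_m`.
#' @param init_mu starting value for `mu_m` (1/h), default 0.03.
#' @param K_s spatial-limitation constant.
#' @param max_iter Nelder-Mead iteration cap.
#' @param tol convergence tolerance on the objective.
#' @return an object of class `sample_fit`: list with `sample_id`,
#'   `mu_m_hat`, `rss`, `n_measure`, `converged`.
#' @export
fit_sample <- function(obs, fixed, init_mu = 0.03, K_s = 24.7,
                       max_iter = 5000, tol = 1e-10) {
  stopifnot(inherits(obs, "tiled_observation"))
  fixed <- as.list(fixed)[c("alpha", "epsilon", "X_m")]
  if (any(vapply(fixed, is.null, logical(1L))))
    stop("fixed must supply alpha, epsilon and X_m")
  use <- obs$times >= 24 - 1e-9
  times <- obs$times[use]
  measured <- obs$total_counts[use]
  if (length(times) < 3L)
    stop("at least 3 timepoints at or after Day 1 are required")
  X0 <- fixed$alpha * obs$X_seed
  objective <- function(mu) {
    r <- mu * (1 - fixed$epsilon * K_s)
    pred <- obs$S * logistic_density(times, r, X0, fixed$X_m)
    sum((measured - pred)^2)
  }
  opt <- stats::optim(init_mu, objective, method = "Nelder-Mead",
                      control = list(maxit = max_iter, abstol = tol,
                                     reltol = tol,
                                     warn.1d.NelderMead = FALSE))
  converged <- opt$convergence == 0L
  if (!converged)
    message("fit_sample: optimizer did not converge for sample '",
            obs$sample_id, "' (code ", opt$convergence, "); fit kept")
  if (opt$par < 0)
    message("fit_sample: negative mu_m fitted for sample '", obs$sample_id, "'")
  structure(
    list(sample_id = obs$sample_id, mu_m_hat = opt$par, rss = opt$value,
         n_measure = length(times), converged = converged),
    class = "sample_fit")
}

#' Aggregate per-sample fits into a growth-rate estimate
#'
#' The estimate of `mu_m` is the mean of the per-sample fitted rates; its
#' spread is the sample (n - 1 denominator) standard deviation. Both feed the
#' prediction-interval calculation.
#'
#' @param fits list of [fit_sample()] results (>= 2).
#' @return an object of class `estimation_result`: list with `mu_m_mean`, `s`,
#'   `n`, and a `fits` data.frame (`sample_id`, `mu_m_hat`, `rss`,
#'   `n_measure`, `converged`).
#' @export
aggregate_fits <- function(fits) {
  if (inherits(fits, "sample_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1L), "sample_fit")))
  if (length(fits) < 2L)
    stop("at least 2 sample fits are required to estimate a spread")
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(sample_id = f$sample_id, mu_m_hat = f$mu_m_hat, rss = f$rss,
               n_measure = f$n_measure, converged = f$converged)))
  structure(
    list(mu_m_mean = mean(df$mu_m_hat), s = stats::sd(df$mu_m_hat),
         n = nrow(df), fits = df),
    class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("Growth-rate estimate: mu_m = %.4g 1/h (s = %.3g, n = %d)\n",
              x$mu_m_mean, x$s, x$n))
  invisible(x)
}

#' Fit all samples of an experiment and aggregate
#'
#' Runs [extract_parameters_all()] over the samples, fixes `alpha`, `epsilon`
#' and `X_m` at their means over the dataset (optionally per seeding
#' density), fits `mu_m` per sample, and aggregates.
#'
#' @param obs_list list of [tiled_observation()] objects.
#' @param by_density fix the parameters at per-seeding-density means instead
#'   of global means.
#' @param ... passed to [fit_sample()].
#' @return an `estimation_result` with the `sample_parameters` table attached
#'   as `$parameters` and the fixed values as `$fixed`.
#' @export
fit_experiment <- function(obs_list, by_density = FALSE, ...) {
  pars <- extract_parameters_all(obs_list)
  if (by_density) {
    fits <- lapply(obs_list, function(o) {
      g <- pars[pars$X_seed == o$X_seed, ]
      fit_sample(o, list(alpha = mean(g$alpha), epsilon = mean(g$epsilon),
                         X_m = mean(g$X_m)), ...)
    })
    fixed <- NULL
  } else {
    fixed <- list(alpha = mean(pars$alpha), epsilon = mean(pars$epsilon),
                  X_m = mean(pars$X_m))
    fits <- lapply(obs_list, fit_sample, fixed = fixed, ...)
  }
  est <- aggregate_fits(fits)
  est$parameters <- pars
  est$fixed <- fixed
  est
}

#' Normalized root-mean-square error for one seeding-density group
#'
#' RMSE over all samples and timepoints of the group, divided by the range
#' (max - min) of the group's measured counts, in percent. All samples must
#' share the prediction timepoints.
#'
#' @param measured_by_sample list of measured count vectors, one per sample,
#'   aligned with `predicted`.
#' @param predicted model-predicted counts at the shared timepoints.
#' @return NRMSE in percent.
#' @export
nrmse <- function(measured_by_sample, predicted) {
  if (is.numeric(measured_by_sample))
    measured_by_sample <- list(measured_by_sample)
  stopifnot(length(measured_by_sample) >= 1L)
  if (!all(lengths(measured_by_sample) == length(predicted)))
    stop("all samples must share the prediction timepoints")
  all_meas <- unlist(measured_by_sample)
  rng <- max(all_meas) - min(all_meas)
  if (!(rng > 0)) stop("NRMSE undefined: measured range is zero")
  sq <- vapply(measured_by_sample,
               function(m) mean((m - predicted)^2), numeric(1L))
  100 * sqrt(mean(sq)) / rng
}

#' Model validation by the 10% NRMSE rule
#'
#' The model passes when the NRMSE between prediction and measurement is
#' below the threshold for every seeding-density group.
#'
#' @param groups named list (one entry per seeding density) of lists with
#'   elements `measured` (list of per-sample count vectors) and `predicted`.
#' @param threshold NRMSE threshold in percent, default 10.
#' @return a data.frame with columns `group`, `nrmse`, `pass`, and attribute
#'   `overall` (logical).
#' @export
validate_model <- function(groups, threshold = 10) {
  stopifnot(length(groups) >= 1L)
  vals <- vapply(groups, function(g) nrmse(g$measured, g$predicted),
                 numeric(1L))
  out <- data.frame(group = names(groups), nrmse = unname(vals),
                    pass = unname(vals) < threshold)
  attr(out, "overall") <- all(out$pass)
  out
}
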