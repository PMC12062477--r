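#' End-to-end design-space determination and validation
#'
#' Runs the full workflow on cultivation data: extract per-sample model
#' inputs from the pre-experiment, fit the maximum specific growth rate per
#' sample and aggregate, compute the prediction interval, Monte-Carlo
#' simulate upper/lower growth limits over the empirical parameter pool,
#' build the probability map over the condition grid, threshold it at the
#' minimum acceptable risk, and - when validation observations are supplied -
#' validate the design space and report R1/R2/R3. NRMSE model checks are
#' computed for the fit (pre-experiment) and the validation data, per
#' seeding density, and Monte-Carlo convergence diagnostics for the map.
#'
#' @param pre list of [tiled_observation()] objects (pre-experiment).
#' @param validation optional list of [tiled_observation()] objects
#'   (validation experiment).
#' @param grid a [condition_grid()] for the probability map.
#' @param spec a [quality_spec()].
#' @param pi minimum acceptable risk (percent).
#' @param M Monte-Carlo iterations.
#' @param seed integer seed for the parameter draw.
#' @param level prediction-interval level.
#' @param mode map mode, `"with_interval"` or `"point_estimate"`.
#' @param nrmse_threshold model-validation NRMSE threshold (percent).
#' @param ... passed to [fit_experiment()].
#' @return an object of class `ds_run`: list with `estimation`, `interval`,
#'   `pool`, `map`, `design_space`, `nrmse_fit`, `nrmse_validation`,
#'   `convergence`, `validation` (a `validation_report`, or `NULL`), `seed`.
#' @export
ds_pipeline <- function(pre, validation = NULL, grid = condition_grid(),
                        spec = quality_spec(), pi = 90, M = 1000,
                        seed = NULL, level = 0.95,
                        mode = "with_interval", nrmse_threshold = 10, ...) {
  est <- fit_experiment(pre, ...)
  bounds <- mu_m_prediction_interval(est, level = level)
  pool <- as_parameter_pool(est$parameters)
  map <- probability_map(grid, pool, bounds, spec = spec, M = M, seed = seed,
                         mode = mode)
  ds <- determine_design_space(map, pi = pi)
  conv <- convergence_summary(map)
  nr_fit <- nrmse_by_density(pre, est)
  out <- list(estimation = est, interval = bounds, pool = pool, map = map,
              design_space = ds, nrmse_fit = nr_fit,
              nrmse_validation = NULL, convergence = conv,
              validation = NULL, seed = seed)
  if (!is.null(validation)) {
    out$nrmse_validation <- nrmse_by_density(validation, est)
    conditions <- observations_to_conditions(validation, grid$t_h_days)
    out$validation <- validate_design_space(ds, conditions, spec = spec)
  }
  class(out) <- "ds_run"
  out
}

#' @export
print.ds_run <- function(x, ...) {
  print(x$estimation)
  print(x$interval)
  print(x$design_space)
  cat(sprintf("Max NRMSE (fit): %.2f%%", max(x$nrmse_fit$nrmse)))
  if (!is.null(x$nrmse_validation))
    cat(sprintf("; max NRMSE (validation): %.2f%%",
                max(x$nrmse_validation$nrmse)))
  cat(sprintf("; max convergence RSD: %.3g%%\n", max(x$convergence$rsd)))
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}

#' Per-density NRMSE between model prediction and measurements
#'
#' Predictions use the estimated mean growth rate and the fixed parameter
#' means from the estimation; measurements are the per-sample totals from
#' Day 1 on.
#'
#' @param obs_list list of [tiled_observation()] objects.
#' @param est an [fit_experiment()] result (needs `$fixed`).
#' @param threshold pass threshold in percent.
#' @return a [validate_model()] data.frame (one row per seeding density).
#' @export
nrmse_by_density <- function(obs_list, est, threshold = 10) {
  stopifnot(inherits(est, "estimation_result"))
  fixed <- est$fixed
  if (is.null(fixed))
    stop("estimation was run per-density; nrmse_by_density needs global means")
  dens <- vapply(obs_list, function(o) o$X_seed, numeric(1L))
  groups <- lapply(split(obs_list, dens), function(g) {
    times <- g[[1L]]$times[g[[1L]]$times >= 24 - 1e-9]
    p <- kinetic_params(mu_m = est$mu_m_mean, alpha = fixed$alpha,
                        epsilon = fixed$epsilon, X_m = fixed$X_m,
                        X_seed = g[[1L]]$X_seed)
    pred <- g[[1L]]$S * closed_form_growth(p, times)
    measured <- lapply(g, function(o) o$total_counts[o$times >= 24 - 1e-9])
    list(measured = measured, predicted = pred)
  })
  validate_model(groups, threshold = threshold)
}

#' Convergence diagnostics of a probability map
#'
#' Applies [convergence_diagnostic()] to the final-time cell numbers of
#' every (seeding density, limit) trajectory set stored in the map.
#'
#' @param map a [probability_map()].
#' @param batches batch count.
#' @return data.frame with columns `X_seed`, `limit`, `rsd` (percent).
#' @export
convergence_summary <- function(map, batches = 10) {
  stopifnot(inherits(map, "probability_map"))
  rows <- list()
  for (xs in names(map$final_counts)) {
    fc <- map$final_counts[[xs]]
    for (lim in names(fc)) {
      rsd <- suppressWarnings(
        convergence_diagnostic(fc[[lim]], batches = batches))
      rows[[paste(xs, lim)]] <- data.frame(X_seed = as.numeric(xs),
                                           limit = lim, rsd = rsd)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write an estimation result or prediction interval to JSON
#'
#' @param x an `estimation_result`, `prediction_interval`, or
#'   `validation_metrics`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  out <- unclass(x)
  out$fits <- NULL; out$parameters <- NULL   # tables go to CSV, not JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a JSON result written by [write_result_json()]
#'
#' @param path JSON path.
#' @return a named list; numeric scalars round-trip at full precision.
#' @export
read_result_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a probability map (and optional design space) as tidy CSV
#'
#' Columns `X_seed`, `t_h_days`, `h` (percent, full precision) and, when a
#' design space is supplied, `in_DS`.
#'
#' @param x a `probability_map` or `design_space`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
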