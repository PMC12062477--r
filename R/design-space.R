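#' Quality specification for harvested cells
#'
#' The acceptance set for the two critical quality attributes: the number of
#' adhesion cells `N` (at least `N_min`, inclusive) and the confluency level
#' `P = X / X_m` (strictly below `P_max`). High confluency degrades cell
#' quality, hence the upper bound.
#'
#' @param N_min minimum acceptable number of adhesion cells, default 5.0e4
#'   (inclusive).
#' @param P_max maximum acceptable confluency, default 0.8 (exclusive).
#' @return an object of class `quality_spec`.
#' @export
quality_spec <- function(N_min = 5.0e4, P_max = 0.8) {
  stopifnot(is.numeric(N_min), N_min > 0,
            is.numeric(P_max), P_max > 0, P_max <= 1)
  structure(list(N_min = N_min, P_max = P_max), class = "quality_spec")
}

#' Does a prediction satisfy the quality specification?
#'
#' `TRUE` iff `N >= N_min` and `P < P_max`. Vectorized; the bounds are
#' inclusive on the cell number and exclusive on the confluency.
#'
#' @param N number(s) of adhesion cells.
#' @param P confluency level(s).
#' @param spec a [quality_spec()].
#' @return logical vector.
#' @export
satisfies_spec <- function(N, P, spec = quality_spec()) {
  stopifnot(inherits(spec, "quality_spec"))
  N >= spec$N_min & P < spec$P_max
}

#' Condition grid over seeding density and harvest time
#'
#' The candidate process-parameter combinations explored for the design
#' space. The default determination grid spans 1500-4500 cells/cm^2 in steps
#' of 375, and harvest times Day 1 to Day 9 every 6 h: 9 x 33 = 297
#' conditions. The validation grid uses the three experimental densities
#' only (3 x 33 = 99 conditions).
#'
#' @param X_seed_values seeding densities (cells/cm^2).
#' @param t_h_days harvest times in days post seeding.
#' @param S culture/imaging area (cm^2) used to convert densities to counts.
#' @return an object of class `condition_grid`.
#' @export
condition_grid <- function(X_seed_values = seq(1500, 4500, by = 375),
                           t_h_days = seq(1, 9, by = 0.25),
                           S = 2.3409) {
  stopifnot(is.numeric(X_seed_values), length(X_seed_values) >= 1L,
            all(X_seed_values > 0),
            is.numeric(t_h_days), length(t_h_days) >= 1L,
            all(t_h_days >= 1), is.numeric(S), S > 0)
  structure(list(X_seed_values = X_seed_values, t_h_days = t_h_days, S = S),
            class = "condition_grid")
}

#' Validation grid preset
#'
#' @param ... overrides passed to [condition_grid()].
#' @return the 3-density x 33-time validation [condition_grid()].
#' @export
validation_grid <- function(...) {
  condition_grid(X_seed_values = c(1500, 3000, 4500), ...)
}

#' Number of conditions in a grid
#' @param grid a [condition_grid()].
#' @return integer count.
#' @export
n_conditions <- function(grid) {
  stopifnot(inherits(grid, "condition_grid"))
  length(grid$X_seed_values) * length(grid$t_h_days)
}

#' Probability map over the condition grid
#'
#' For every (seeding density, harvest time) combination, the probability
#' that the predicted quality attributes satisfy the specification, estimated
#' over `M` Monte-Carlo draws from the empirical parameter pool. One shared
#' parameter matrix is used across the whole grid, and one pair of
#' trajectories per (row, seeding density) supplies all harvest times.
#'
#' In `with_interval` mode (the headline method) an iteration counts as a
#' success only when the predictions at *both* the upper and the lower
#' prediction-interval bound of the growth rate satisfy the specification,
#' making the map conservative with respect to rate uncertainty. In
#' `point_estimate` mode (the reference method) the mean rate alone is used.
#' Since the acceptance set is an interval in the cell density and the
#' density is monotone in the rate, `with_interval` probabilities are never
#' above `point_estimate` probabilities at a shared parameter matrix.
#'
#' The confluency of each iteration uses that iteration's own `X_m`.
#'
#' @param grid a [condition_grid()].
#' @param pool a [parameter_pool()].
#' @param pi_bounds a [mu_m_prediction_interval()].
#' @param spec a [quality_spec()].
#' @param M Monte-Carlo iterations, default 1000.
#' @param seed optional integer seed for the parameter draw.
#' @param mode `"with_interval"` (default) or `"point_estimate"`.
#' @param theta optional pre-drawn [sample_theta()] matrix (overrides `M`,
#'   `seed`); lets both modes share one draw exactly.
#' @param K_s spatial-limitation constant.
#' @param sampling_mode passed to [sample_theta()].
#' @return an object of class `probability_map`: list with matrix `h`
#'   (`n_Xseed x n_th`, percent, dimnames set), `grid`, `M`, `mode`, `seed`,
#'   `theta`, and `final_counts` (list per density of the final-time upper
#'   and lower cell numbers, for convergence diagnostics).
#' @export
probability_map <- function(grid, pool, pi_bounds, spec = quality_spec(),
                            M = 1000, seed = NULL,
                            mode = c("with_interval", "point_estimate"),
                            theta = NULL, K_s = 24.7,
                            sampling_mode = "independent") {
  stopifnot(inherits(grid, "condition_grid"))
  mode <- match.arg(mode)
  if (is.null(theta))
    theta <- sample_theta(pool, M, seed = seed, mode = sampling_mode)
  M <- theta$M
  t_grid <- 24 * grid$t_h_days
  nt <- length(t_grid)
  h <- matrix(NA_real_, nrow = length(grid$X_seed_values), ncol = nt,
              dimnames = list(X_seed = grid$X_seed_values,
                              t_h_days = grid$t_h_days))
  final_counts <- vector("list", length(grid$X_seed_values))
  names(final_counts) <- grid$X_seed_values
  for (k in seq_along(grid$X_seed_values)) {
    xs <- grid$X_seed_values[k]
    if (mode == "with_interval") {
      lim <- simulate_limits(xs, theta, pi_bounds, t_grid, K_s = K_s)
      ok <- satisfies_spec(grid$S * lim$X_up, lim$X_up / theta$X_m, spec) &
            satisfies_spec(grid$S * lim$X_lo, lim$X_lo / theta$X_m, spec)
      final_counts[[k]] <- list(up = grid$S * lim$X_up[, nt],
                                lo = grid$S * lim$X_lo[, nt])
    } else {
      X <- limit_matrix(xs, theta, pi_bounds$mean, t_grid, K_s, "analytic")
      ok <- satisfies_spec(grid$S * X, X / theta$X_m, spec)
      final_counts[[k]] <- list(mean = grid$S * X[, nt])
    }
    h[k, ] <- 100 * colMeans(ok)
  }
  structure(list(h = h, grid = grid, M = M, mode = mode,
                 seed = theta$seed, theta = theta,
                 final_counts = final_counts, spec = spec,
                 pi_bounds = pi_bounds),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("Probability map (%s, M = %d): %d x %d conditions, h in [%.1f, %.1f]%%\n",
              x$mode, x$M, nrow(x$h), ncol(x$h), min(x$h), max(x$h)))
  invisible(x)
}

#' Threshold a probability map into a design space
#'
#' The design space at minimum acceptable risk `pi` is the set of conditions
#' whose predicted probability is at least `pi` percent (inclusive).
#'
#' @param map a [probability_map()].
#' @param pi minimum acceptable risk in percent, in (0, 100].
#' @return an object of class `design_space`: list with logical matrix
#'   `mask`, `pi`, and the source `map`.
#' @export
determine_design_space <- function(map, pi = 90) {
  stopifnot(inherits(map, "probability_map"),
            is.numeric(pi), length(pi) == 1L)
  if (!(pi > 0 && pi <= 100)) stop("pi must be in (0, 100]")
  structure(list(mask = map$h >= pi, pi = pi, map = map),
            class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat(sprintf("Design space at pi = %g%%: %d of %d conditions feasible\n",
              x$pi, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Tidy export of a probability map (optionally with its design space)
#'
#' @param x a [probability_map()] or [determine_design_space()] result.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return data.frame with columns `X_seed`, `t_h_days`, `h`, and `in_DS`
#'   when a design space is given.
#' @export
as.data.frame.probability_map <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  g <- x$grid
  data.frame(X_seed = rep(g$X_seed_values, times = length(g$t_h_days)),
             t_h_days = rep(g$t_h_days, each = length(g$X_seed_values)),
             h = as.vector(x$h))
}

#' @export
as.data.frame.design_space <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  out <- as.data.frame(x$map)
  out$in_DS <- as.vector(x$mask)
  out
}
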