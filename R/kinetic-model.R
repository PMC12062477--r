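#' Kinetic parameters for the adherent-cell growth model
#'
#' Bundles everything the growth model needs to produce one curve: the maximum
#' specific growth rate `mu_m`, the spatial-limitation constant `K_s`, the
#' adhesion ratio `alpha` (fraction of seeded cells attached on Day 1), the
#' seeding heterogeneity `epsilon` (population SD of normalized per-tile Day 1
#' counts), the saturation density `X_m`, and the seeding density `X_seed`.
#'
#' The model starts its clock on Day 1 (24 h post seeding) at
#' `X0 = alpha * X_seed` and evolves `dX/dt = mu(X) * X` with
#' `mu(X) = mu_m * (1 - epsilon * K_s) * (1 - X / X_m)`.
#'
#' The effective intrinsic rate `mu_m * (1 - epsilon * K_s)` may be
#' negative when `epsilon * K_s > 1`; this is permitted (it is what the model
#' equations say) but flagged via the `negative_rate` field and a warning,
#' because it usually signals a data problem.
#'
#' @param mu_m maximum specific growth rate (1/h), >= 0.
#' @param alpha adhesion ratio, in (0, 1].
#' @param epsilon seeding heterogeneity, >= 0.
#' @param X_m saturation (maximum) cell density (cells/cm^2), > 0.
#' @param X_seed seeding density (cells/cm^2), > 0.
#' @param K_s spatial-limitation constant (dimensionless); the literature
#'   value 24.7 is the default.
#' @return an object of class `kinetic_params`.
#' @export
#' @examples
#' p <- kinetic_params(mu_m = 0.0276, alpha = 0.9, epsilon = 0.004,
#'                     X_m = 45000, X_seed = 3000)
#' initial_density(p)
kinetic_params <- function(mu_m, alpha, epsilon, X_m, X_seed, K_s = 24.7) {
  stopifnot(is.numeric(mu_m), length(mu_m) == 1L, is.finite(mu_m),
            is.numeric(alpha), length(alpha) == 1L,
            is.numeric(epsilon), length(epsilon) == 1L,
            is.numeric(X_m), length(X_m) == 1L,
            is.numeric(X_seed), length(X_seed) == 1L,
            is.numeric(K_s), length(K_s) == 1L)
  if (!(X_m > 0)) stop("X_m must be > 0")
  if (!(X_seed > 0)) stop("X_seed must be > 0")
  if (mu_m < 0) stop("mu_m must be >= 0")
  if (K_s < 0) stop("K_s must be >= 0")
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (epsilon < 0) stop("epsilon must be >= 0")
  r <- mu_m * (1 - epsilon * K_s)
  negative_rate <- r < 0
  if (negative_rate)
    warning("effective growth rate mu_m * (1 - epsilon * K_s) is negative ",
            "(epsilon * K_s = ", format(epsilon * K_s), ")")
  structure(
    list(mu_m = mu_m, K_s = K_s, alpha = alpha, epsilon = epsilon,
         X_m = X_m, X_seed = X_seed, r = r, negative_rate = negative_rate),
    class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters:\n")
  cat(sprintf("  mu_m    = %.4g 1/h   (effective rate r = %.4g 1/h%s)\n",
              x$mu_m, x$r, if (x$negative_rate) ", NEGATIVE" else ""))
  cat(sprintf("  K_s     = %.4g\n  alpha   = %.4g\n  epsilon = %.4g\n",
              x$K_s, x$alpha, x$epsilon))
  cat(sprintf("  X_m     = %.6g cells/cm^2\n  X_seed  = %.6g cells/cm^2\n",
              x$X_m, x$X_seed))
  invisible(x)
}

#' Cell density on Day 1
#'
#' The initial condition of the growth model: the density of cells attached
#' 24 h after seeding, `X0 = alpha * X_seed`.
#'
#' @param params a [kinetic_params()] object.
#' @return Day 1 adhesion-cell density (cells/cm^2).
#' @export
initial_density <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$alpha * params$X_seed
}

#' Specific growth rate at a given cell density
#'
#' `mu(X) = mu_m * (1 - epsilon * K_s) * (1 - X / X_m)`: the intrinsic rate
#' penalized once for seeding heterogeneity (spatial limitation) and once for
#' contact inhibition. May be negative when `epsilon * K_s > 1` or `X > X_m`.
#'
#' @param params a [kinetic_params()] object.
#' @param X adhesion-cell density (cells/cm^2), >= 0; vectorized.
#' @return specific growth rate(s) (1/h).
#' @export
specific_growth_rate <- function(params, X) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(X))
  if (any(X < 0)) stop("X must be >= 0")
  params$r * (1 - X / params$X_m)
}

#' Closed-form solution of the growth model
#'
#' The ODE `dX/dt = r * X * (1 - X/X_m)` with `X(24 h) = alpha * X_seed` is a
#' logistic equation with the analytic solution
#' `X(t) = X_m * X0 * exp(r (t - 24)) / (X_m + X0 * (exp(r (t - 24)) - 1))`.
#' This is the reference against which the numerical integrator is checked,
#' and the fast path used by the Monte-Carlo stages.
#'
#' @param params a [kinetic_params()] object.
#' @param t time(s) in hours since seeding, >= 24; vectorized.
#' @return adhesion-cell density (cells/cm^2) at each `t`.
#' @export
closed_form_growth <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(t))
  if (any(t < 24)) stop("t must be >= 24 h (the model starts on Day 1)")
  X0 <- initial_density(params)
  logistic_density(t, params$r, X0, params$X_m)
}

# Vectorized logistic kernel shared by the closed form and the Monte-Carlo
# stages. Written to be safe for r <= 0 and for large r * t (the exp overflow
# limit is the saturation X_m).
logistic_density <- function(t, r, X0, X_m) {
  E <- exp(r * (t - 24))
  X <- X_m * X0 * E / (X_m + X0 * (E - 1))
  # E = Inf (very large r * t) gives NaN above but the limit is X_m
  bad <- is.infinite(E)
  if (any(bad)) X[bad] <- rep_len(X_m, length(X))[bad]
  X
}

#' Simulate the growth curve on a time grid
#'
#' Integrates the growth model from Day 1 over the requested grid. The default
#' route is numerical integration with [deSolve::ode()] (`lsoda`,
#' `rtol = 1e-8`, `atol = 1e-6`); `method = "analytic"` evaluates the
#' closed-form logistic solution instead. The two agree to better than 1e-6
#' relative error (a tested invariant), so either can be used interchangeably.
#'
#' @param params a [kinetic_params()] object.
#' @param t_grid ascending times in hours since seeding; the first entry must
#'   be >= 24 h.
#' @param method `"ode"` (numerical, default) or `"analytic"`.
#' @return an object of class `growth_curve`: a data.frame with columns
#'   `time_h` and `density` (cells/cm^2).
#' @export
#' @examples
#' p <- kinetic_params(mu_m = 0.0276, alpha = 0.9, epsilon = 0,
#'                     X_m = 45000, X_seed = 3000)
#' gc <- simulate_growth(p, seq(24, 216, by = 6))
#' head(gc)
simulate_growth <- function(params, t_grid, method = c("ode", "analytic")) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(t_grid),
            length(t_grid) >= 1L)
  method <- match.arg(method)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly ascending")
  if (t_grid[1L] < 24)
    stop("t_grid must start at or after 24 h (Day 1)")
  X0 <- initial_density(params)
  if (method == "analytic") {
    dens <- closed_form_growth(params, t_grid)
  } else {
    times <- if (t_grid[1L] > 24) c(24, t_grid) else t_grid
    rhs <- function(t, y, parms) {
      list(parms$r * y * (1 - y / parms$X_m))
    }
    sol <- deSolve::ode(y = c(X = X0), times = times, func = rhs,
                        parms = params, method = "lsoda",
                        rtol = 1e-8, atol = 1e-6)
    dens <- sol[match(t_grid, times), "X"]
  }
  structure(data.frame(time_h = t_grid, density = as.numeric(dens)),
            class = c("growth_curve", "data.frame"))
}
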