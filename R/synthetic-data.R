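#' Configuration of the synthetic-experiment generator
#'
#' The generator emulates the tiled image-based counting data the workflow
#' consumes: three seeding densities, six replicate wells per density per
#' operator, counts every 6 h from Day 1 to Day 9 resolved into 64 imaging
#' tiles. Per sample it draws a true maximum specific growth rate, adhesion
#' ratio and saturation density, allocates the Day 1 cells to tiles through a
#' symmetric Dirichlet-multinomial (whose concentration controls the realized
#' seeding heterogeneity), propagates the total density with the logistic
#' growth model, and perturbs later counts with multiplicative lognormal
#' noise.
#'
#' Default values printed in the study design are taken as-is (densities
#' 1500/3000/4500 cells/cm^2, 6 replicates, operators A/B/C, growth rate
#' 2.76e-2 +/- 1.46e-3 1/h, 6-h imaging from Day 1 to Day 9, S = 2.3409 cm^2,
#' K_s = 24.7). The remaining distributions are calibrated so the analysis
#' pipeline reproduces the qualitative design-space structure of a healthy
#' MSC expansion (feasible harvest windows around Days 7.5-8, 6-7 and
#' 5.5-6.5 at 1500, 3000 and 4500 cells/cm^2): adhesion ratio ~ Beta(mean
#' 0.75, concentration 100), saturation density ~ Normal(45000, 1000)
#' truncated positive, Dirichlet concentration 45 (realized heterogeneity
#' ~ 0.0023), counting noise CV 5%.
#'
#' @param seeding_densities cells/cm^2.
#' @param replicates wells per density per operator.
#' @param operators operator labels.
#' @param mu_m_mean,mu_m_sd Normal distribution of the true growth rate (1/h).
#' @param alpha_mean,alpha_conc Beta distribution of the adhesion ratio
#'   (shape1 = mean * conc, shape2 = (1 - mean) * conc).
#' @param heterogeneity_dirichlet_conc symmetric Dirichlet concentration of
#'   the per-tile seeding allocation; larger values give more uniform seeding
#'   and smaller realized heterogeneity.
#' @param X_m_mean,X_m_sd Normal (truncated > 0) distribution of the
#'   saturation density (cells/cm^2).
#' @param count_noise_cv coefficient of variation of the multiplicative
#'   lognormal counting noise applied to post-Day 1 totals.
#' @param tile_noise `"lognormal"` (default: totals perturbed, tiles
#'   redistributed multinomially) or `"poisson"` (independent per-tile
#'   Poisson counts).
#' @param operator_mu_offset named numeric vector of per-operator additive
#'   offsets on the true growth rate (1/h); default no offset.
#' @param S imaged area (cm^2).
#' @param time_step_h imaging interval (h).
#' @param horizon_days end of cultivation (days).
#' @param K_s spatial-limitation constant used for propagation.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seeding_densities = c(1500, 3000, 4500),
                             replicates = 6,
                             operators = c("A", "B", "C"),
                             mu_m_mean = 2.76e-2, mu_m_sd = 1.46e-3,
                             alpha_mean = 0.75, alpha_conc = 100,
                             heterogeneity_dirichlet_conc = 45,
                             X_m_mean = 45000, X_m_sd = 1000,
                             count_noise_cv = 0.05,
                             tile_noise = c("lognormal", "poisson"),
                             operator_mu_offset = NULL,
                             S = 2.3409, time_step_h = 6, horizon_days = 9,
                             K_s = 24.7) {
  tile_noise <- match.arg(tile_noise)
  stopifnot(all(seeding_densities > 0), replicates >= 1,
            length(operators) >= 1L, mu_m_mean > 0, mu_m_sd >= 0,
            alpha_mean > 0, alpha_mean <= 1, alpha_conc > 0,
            heterogeneity_dirichlet_conc > 0, X_m_mean > 0, X_m_sd >= 0,
            count_noise_cv >= 0, S > 0, time_step_h > 0, horizon_days > 1)
  if (is.null(operator_mu_offset))
    operator_mu_offset <- stats::setNames(numeric(length(operators)),
                                          operators)
  structure(
    list(seeding_densities = seeding_densities, replicates = replicates,
         operators = operators, mu_m_mean = mu_m_mean, mu_m_sd = mu_m_sd,
         alpha_mean = alpha_mean, alpha_conc = alpha_conc,
         heterogeneity_dirichlet_conc = heterogeneity_dirichlet_conc,
         X_m_mean = X_m_mean, X_m_sd = X_m_sd,
         count_noise_cv = count_noise_cv, tile_noise = tile_noise,
         operator_mu_offset = operator_mu_offset,
         S = S, time_step_h = time_step_h, horizon_days = horizon_days,
         K_s = K_s),
    class = "generator_config")
}

# Imaging grid: Day 1 to the horizon, every time_step_h hours.
generator_times <- function(cfg) {
  seq(24, 24 * cfg$horizon_days, by = cfg$time_step_h)
}

rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc, rate = 1)
  g / sum(g)
}

# Multinomial allocation with a per-tile capacity: overflow above the local
# saturation cap is re-seeded into the remaining tiles until everything is
# placed (or every tile is full).
capped_multinomial <- function(total, p, cap) {
  total <- min(total, 64L * cap)
  alloc <- as.vector(stats::rmultinom(1L, total, p))
  repeat {
    over <- alloc - cap
    excess <- sum(over[over > 0])
    if (excess == 0) break
    alloc <- pmin(alloc, cap)
    free <- which(alloc < cap)
    if (!length(free)) break
    alloc[free] <- alloc[free] +
      as.vector(stats::rmultinom(1L, excess, p[free]))
  }
  alloc
}

rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Generate one synthetic cultivated sample
#'
#' Draws the sample's true parameters, allocates the Day 1 cells to the 64
#' tiles, propagates total growth with the closed-form logistic model driven
#' by the *realized* Day 1 state (attached density and measured-from-tiles
#' heterogeneity, mirroring how the analysis defines these quantities), and
#' emits the observed tile counts. Day 1 tile counts are the allocation
#' itself; later totals carry multiplicative lognormal counting noise (capped
#' so the density never exceeds the sample's saturation density) and are
#' redistributed to tiles multinomially following the seeding pattern,
#' subject to a per-tile capacity of `S / 64 * X_m` cells: locally dense
#' tiles saturate first (local contact inhibition), so the maximum-tile
#' saturation-density estimator reads the sample's true `X_m` once the
#' culture matures.
#'
#' Uses the current RNG state; seed at the caller ([generate_experiment()]
#' does).
#'
#' @param cfg a [generator_config()].
#' @param X_seed seeding density (cells/cm^2).
#' @param operator operator label (selects the growth-rate offset).
#' @param sample_id sample label.
#' @return list with `obs` (a [tiled_observation()]) and `truth` (one-row
#'   data.frame: `sample_id`, `operator`, `X_seed`, `mu_m`, `alpha`,
#'   `epsilon_realized`, `X_m`).
#' @export
generate_sample <- function(cfg, X_seed, operator = cfg$operators[1L],
                            sample_id = "S1") {
  stopifnot(inherits(cfg, "generator_config"))
  times <- generator_times(cfg)
  mu <- stats::rnorm(1L, cfg$mu_m_mean, cfg$mu_m_sd) +
    if (operator %in% names(cfg$operator_mu_offset))
      cfg$operator_mu_offset[[operator]] else 0
  alpha <- stats::rbeta(1L, cfg$alpha_mean * cfg$alpha_conc,
                        (1 - cfg$alpha_mean) * cfg$alpha_conc)
  X_m <- rnorm_pos(1L, cfg$X_m_mean, cfg$X_m_sd)
  # Day 1 allocation: Dirichlet tile propensities, multinomial placement
  n_day1 <- round(alpha * cfg$S * X_seed)
  p_seed <- rdirichlet1(64L, cfg$heterogeneity_dirichlet_conc)
  tiles1 <- as.vector(stats::rmultinom(1L, n_day1, p_seed))
  alpha_real <- n_day1 / (cfg$S * X_seed)
  eps_real <- sqrt(mean((tiles1 / n_day1 - 1 / 64)^2))
  # propagate the realized Day 1 state with the growth model
  r <- mu * (1 - eps_real * cfg$K_s)
  X0 <- n_day1 / cfg$S
  Xt <- logistic_density(times, r, X0, X_m)
  N_model <- cfg$S * Xt
  # observed totals: Day 1 exact, later frames with counting noise
  cv <- cfg$count_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  noise <- c(1, stats::rlnorm(length(times) - 1L, -sdlog^2 / 2, sdlog))
  totals <- round(pmin(N_model * noise, cfg$S * X_m))
  totals[1L] <- n_day1
  # tile-level counts: allocation relaxes toward uniform with confluency
  tile_counts <- matrix(0L, nrow = length(times), ncol = 64L)
  tile_counts[1L, ] <- tiles1
  cap <- ceiling(cfg$S * X_m / 64)           # local (per-tile) capacity
  for (j in seq_along(times)[-1L]) {
    if (cfg$tile_noise == "poisson") {
      tile_counts[j, ] <- stats::rpois(64L, pmin(N_model[j] * p_seed, cap))
      totals[j] <- sum(tile_counts[j, ])
    } else {
      tile_counts[j, ] <- capped_multinomial(totals[j], p_seed, cap)
    }
  }
  obs <- tiled_observation(sample_id, operator, X_seed, times,
                           tile_counts = tile_counts, S = cfg$S)
  truth <- data.frame(sample_id = sample_id, operator = operator,
                      X_seed = X_seed, mu_m = mu, alpha = alpha_real,
                      epsilon_realized = eps_real, X_m = X_m)
  list(obs = obs, truth = truth)
}

#' Generate a complete synthetic experiment
#'
#' All operators x seeding densities x replicates (default 3 x 3 x 6 = 54
#' samples, 33 timepoints each), fully determined by `seed`. The per-sample
#' generating parameters are returned as the truth table for
#' parameter-recovery testing.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @param operators subset of `cfg$operators` to generate (e.g. a single
#'   pre-experiment operator).
#' @return an object of class `synthetic_experiment`: list with
#'   `observations` (named list of [tiled_observation()]), `truth`
#'   (data.frame), `seed`, `config`.
#' @export
generate_experiment <- function(cfg = generator_config(), seed = 1L,
                                operators = cfg$operators) {
  stopifnot(inherits(cfg, "generator_config"),
            all(operators %in% cfg$operators))
  set.seed(seed)
  obs <- list()
  truth <- list()
  for (op in operators) {
    for (xs in cfg$seeding_densities) {
      for (rep_i in seq_len(cfg$replicates)) {
        id <- sprintf("%s_x%d_r%d", op, as.integer(xs), rep_i)
        smp <- generate_sample(cfg, xs, operator = op, sample_id = id)
        obs[[id]] <- smp$obs
        truth[[id]] <- smp$truth
      }
    }
  }
  structure(list(observations = obs,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 seed = seed, config = cfg),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("Synthetic experiment: %d samples, %d timepoints each (seed %d)\n",
              length(x$observations),
              length(x$observations[[1L]]$times), x$seed))
  invisible(x)
}

#' Split a synthetic experiment by operator
#'
#' @param exp_ a [generate_experiment()] result.
#' @return named list of observation lists, one entry per operator.
#' @export
split_by_operator <- function(exp_) {
  stopifnot(inherits(exp_, "synthetic_experiment"))
  ops <- vapply(exp_$observations, function(o) o$operator, character(1L))
  lapply(split(seq_along(ops), ops), function(i) exp_$observations[i])
}
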