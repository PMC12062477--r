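# Shared fixture builders. Everything is generated in code; no data files.

# A well with perfectly uniform tiles: `per_tile` cells in each of the 64
# tiles at every timepoint (constant over time unless `growth` is given).
uniform_obs <- function(per_tile = 100, times = c(24, 48, 72), X_seed = 2000,
                        S = 2.3409, growth = rep(1, length(times)),
                        sample_id = "U1") {
  m <- outer(growth, rep(per_tile, 64))
  tiled_observation(sample_id, "A", X_seed, times, tile_counts = m, S = S)
}

# A well whose Day 1 cells all sit in a single tile.
one_hot_obs <- function(n_cells = 3000, times = c(24, 48), X_seed = 2000,
                        S = 2.3409) {
  m <- matrix(0, nrow = length(times), ncol = 64)
  m[, 1] <- n_cells
  tiled_observation("H1", "A", X_seed, times, tile_counts = m, S = S)
}

# Noise-free observation generated directly from the growth model, for
# inverse-crime fitting tests.
model_obs <- function(mu_m, alpha, epsilon, X_m, X_seed,
                      times = seq(24, 216, by = 6), S = 2.3409,
                      sample_id = "M1") {
  p <- suppressWarnings(kinetic_params(mu_m = mu_m, alpha = alpha,
                                       epsilon = epsilon, X_m = X_m,
                                       X_seed = X_seed))
  totals <- S * closed_form_growth(p, times)
  tiled_observation(sample_id, "A", X_seed, times, total_counts = totals,
                    S = S)
}

# Default-calibrated pre-experiment (one operator, 18 samples) plus its
# fitted estimation, interval and pool; memoised per seed within a test run.
pre_experiment_fixture <- local({
  cache <- list()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      exp_ <- generate_experiment(generator_config(), seed = seed,
                                  operators = "A")
      est <- fit_experiment(exp_$observations)
      cache[[key]] <<- list(
        experiment = exp_, estimation = est,
        interval = mu_m_prediction_interval(est),
        pool = as_parameter_pool(est$parameters))
    }
    cache[[key]]
  }
})
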