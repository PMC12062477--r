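test_that("theta sampling honours pool contents, seed and mode", {
  single <- parameter_pool(0.8, 0.004, 42000)
  th <- sample_theta(single, 50, seed = 1)
  expect_true(all(th$alpha == 0.8 & th$epsilon == 0.004 & th$X_m == 42000))
  pool <- parameter_pool(alphas = c(0.7, 0.8, 0.9),
                         epsilons = c(0.001, 0.002, 0.003),
                         X_ms = c(40000, 45000, 50000))
  a <- sample_theta(pool, 1000, seed = 42)
  b <- sample_theta(pool, 1000, seed = 42)
  expect_identical(a, b)
  # joint mode keeps per-sample triples together
  j <- sample_theta(pool, 500, seed = 3, mode = "joint")
  triples <- paste(j$alpha, j$epsilon, j$X_m)
  allowed <- paste(pool$alphas, pool$epsilons, pool$X_ms)
  expect_true(all(triples %in% allowed))
  # independent mode produces combinations outside the original triples
  ind <- sample_theta(pool, 500, seed = 3, mode = "independent")
  expect_false(all(paste(ind$alpha, ind$epsilon, ind$X_m) %in% allowed))
})

test_that("theta column means approach the pool means", {
  set.seed(8)
  pool <- parameter_pool(alphas = runif(18, 0.6, 0.9),
                         epsilons = runif(18, 0.001, 0.004),
                         X_ms = runif(18, 40000, 50000))
  th <- sample_theta(pool, 4000, seed = 77)
  for (col in c("alphas", "epsilons", "X_ms")) {
    v <- pool[[col]]
    mc <- th[[sub("s$", "", sub("X_ms", "X_m", col))]]
    se <- sd(v) / sqrt(length(mc))
    expect_lt(abs(mean(mc) - mean(v)), 3 * se + 1e-12)
  }
})

test_that("upper-limit trajectories dominate lower-limit trajectories", {
  fx <- pre_experiment_fixture()
  th <- sample_theta(fx$pool, 200, seed = 5)
  lim <- simulate_limits(3000, th, fx$interval, seq(24, 216, by = 6))
  expect_true(all(lim$X_up >= lim$X_lo - 1e-9))
  # collapsed interval: the two limits coincide row by row
  flat <- mu_m_prediction_interval(list(mean = fx$interval$mean, s = 0,
                                        n = fx$interval$n))
  lim0 <- simulate_limits(3000, th, flat, c(24, 120, 216))
  expect_equal(lim0$X_up, lim0$X_lo)
})

test_that("limit trajectories agree with the closed-form oracle", {
  th <- sample_theta(parameter_pool(0.82, 0.0031, 43000), 1, seed = 1)
  bounds <- mu_m_prediction_interval(list(mean = 0.0276, s = 1.46e-3, n = 18))
  tg <- c(24, 120, 216)
  lim <- simulate_limits(2500, th, bounds, tg)
  for (mu in c(bounds$upper, bounds$lower)) {
    p <- kinetic_params(mu_m = mu, alpha = 0.82, epsilon = 0.0031,
                        X_m = 43000, X_seed = 2500)
    side <- if (mu == bounds$upper) lim$X_up else lim$X_lo
    expect_lt(max(abs(side[1, ] - closed_form_growth(p, tg)) /
                    closed_form_growth(p, tg)), 1e-6)
  }
  # and the numerical-integration route agrees with the analytic one
  lim_ode <- simulate_limits(2500, th, bounds, tg, method = "ode")
  expect_equal(lim_ode$X_up, lim$X_up, tolerance = 1e-6)
})

test_that("late-time limit spread shrinks with seeding density", {
  # denser seeding saturates earlier, damping growth-rate variability
  fx <- pre_experiment_fixture()
  th <- sample_theta(fx$pool, 400, seed = 9)
  tg <- seq(24, 216, by = 24)
  gap_at <- function(X_seed) {
    lim <- simulate_limits(X_seed, th, fx$interval, tg)
    mean(lim$X_up[, length(tg)] - lim$X_lo[, length(tg)])
  }
  expect_gt(gap_at(1500), gap_at(4500))
})

test_that("trajectory export is tidy and faithful to the matrices", {
  th <- sample_theta(parameter_pool(c(0.7, 0.8), c(0.002, 0.003),
                                    c(44000, 46000)), 5, seed = 2)
  bounds <- mu_m_prediction_interval(list(mean = 0.0276, s = 1e-3, n = 18))
  lim <- simulate_limits(3000, th, bounds, c(24, 120, 216))
  df <- as.data.frame(lim)
  expect_equal(nrow(df), 15)
  expect_equal(df$X_up[df$iteration == 3 & df$time_h == 120],
               lim$X_up[3, 2])
  expect_true(all(df$X_up >= df$X_lo))
})

test_that("convergence diagnostic behaves like a relative standard error", {
  expect_equal(convergence_diagnostic(rep(1000, 100)), 0)
  # i.i.d. counts with known CV: diagnostic ~ 100 * CV / sqrt(M)
  set.seed(55)
  M <- 1000; cv <- 0.10
  reps <- replicate(40, {
    x <- rnorm(M, 1e5, cv * 1e5)
    suppressWarnings(convergence_diagnostic(x))
  })
  expected <- 100 * cv / sqrt(M)
  expect_gt(mean(reps), expected / 2)
  expect_lt(mean(reps), expected * 2)
  # grows tighter as M grows
  set.seed(56)
  big <- mean(replicate(20, suppressWarnings(
    convergence_diagnostic(rnorm(8000, 1e5, 1e4)))))
  small <- mean(replicate(20, suppressWarnings(
    convergence_diagnostic(rnorm(250, 1e5, 1e4)))))
  expect_lt(big, small)
  expect_error(convergence_diagnostic(rnorm(15), batches = 10), "at least")
  expect_warning(convergence_diagnostic(rnorm(100, 100, 50)), "exceeds")
})
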