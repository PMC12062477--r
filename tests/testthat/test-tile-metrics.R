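test_that("adhesion ratio is Day 1 tile sum over seeded cells", {
  S <- 2.3409; X_seed <- 2000
  # full adhesion: Day 1 sum equals the seeded count
  full <- uniform_obs(per_tile = S * X_seed / 64, X_seed = X_seed, S = S)
  expect_equal(adhesion_ratio(full), 1.0)
  none <- uniform_obs(per_tile = 0, X_seed = X_seed, S = S)
  expect_equal(adhesion_ratio(none), 0.0)
  # hand arithmetic: 3511 / (2.3409 * 2000)
  m <- matrix(0, 2, 64); m[1, ] <- c(rep(55, 54), rep(54, 9), 55)
  stopifnot(sum(m[1, ]) == 3511)
  m[2, ] <- m[1, ]
  obs <- tiled_observation("X", "A", X_seed, c(24, 48), tile_counts = m, S = S)
  expect_equal(adhesion_ratio(obs), 3511 / (S * X_seed), tolerance = 1e-12)
  expect_equal(adhesion_ratio(obs), 0.74997, tolerance = 1e-4)
})

test_that("seeding heterogeneity matches direct evaluation of the tile formula", {
  expect_equal(seeding_heterogeneity(uniform_obs(100)), 0)
  # one-hot seeding: closed form sqrt(63)/64
  expect_equal(seeding_heterogeneity(one_hot_obs()), sqrt(63) / 64,
               tolerance = 1e-12)
  expect_equal(seeding_heterogeneity(one_hot_obs()), 0.12402, tolerance = 1e-4)
  # fractions (0.5, 0.5/63, ..., 0.5/63) via counts (630, 10, ..., 10)
  counts <- c(630, rep(10, 63))
  m <- rbind(counts, counts)
  obs <- tiled_observation("F", "A", 2000, c(24, 48), tile_counts = m)
  f <- counts / sum(counts)
  expected <- sqrt(mean((f - 1 / 64)^2))   # direct formula on the fractions
  expect_equal(seeding_heterogeneity(obs), expected, tolerance = 1e-12)
})

test_that("heterogeneity is invariant to rescaling Day 1 counts", {
  set.seed(3)
  counts <- rpois(64, 80)
  m1 <- rbind(counts, counts)
  m2 <- rbind(counts * 7L, counts * 7L)
  o1 <- tiled_observation("a", "A", 2000, c(24, 48), tile_counts = m1)
  o2 <- tiled_observation("b", "A", 2000, c(24, 48), tile_counts = m2)
  expect_equal(seeding_heterogeneity(o1), seeding_heterogeneity(o2))
})

test_that("maximum cell density scales the densest tile to the full area", {
  S <- 2.3409
  m <- matrix(0, 3, 64); m[2, 17] <- 1000
  obs <- tiled_observation("X", "A", 2000, c(24, 48, 72), tile_counts = m,
                           S = S)
  expect_equal(max_cell_density(obs), 64 * 1000 / S, tolerance = 1e-12)
  expect_equal(max_cell_density(obs), 27340.8, tolerance = 1e-4)
  # constant counts: any timepoint gives the same maximum
  expect_equal(max_cell_density(uniform_obs(100)), 64 * 100 / 2.3409)
  # increasing counts: the final timepoint determines the maximum
  grow <- uniform_obs(per_tile = 50, growth = c(1, 2, 4))
  expect_equal(max_cell_density(grow), 64 * 200 / 2.3409)
})

test_that("extract_parameters composes the three metrics", {
  S <- 2.3409; X_seed <- 2000
  full <- uniform_obs(per_tile = S * X_seed / 64, X_seed = X_seed, S = S)
  p <- extract_parameters(full)
  expect_equal(p$alpha, 1)
  expect_equal(p$epsilon, 0)
  expect_equal(p$X_m, 64 * max(full$tile_counts) / S)
  expect_equal(seeding_heterogeneity(one_hot_obs()), 0.124, tolerance = 1e-3)
})

test_that("alpha recovery error is bounded by the rounding quantum", {
  set.seed(11)
  for (i in 1:20) {
    alpha_true <- runif(1, 0.5, 1)
    X_seed <- sample(c(1500, 3000, 4500), 1)
    S <- 2.3409
    total <- round(alpha_true * S * X_seed)
    counts <- as.vector(rmultinom(1, total, rep(1 / 64, 64)))
    obs <- tiled_observation("r", "A", X_seed, c(24, 48),
                             tile_counts = rbind(counts, counts), S = S)
    expect_lt(abs(adhesion_ratio(obs) - alpha_true), 1 / (S * X_seed))
  }
})

test_that("generator-scale wells recover alpha and epsilon", {
  set.seed(5)
  cfg <- generator_config(count_noise_cv = 0)
  smp <- generate_sample(cfg, 3000)
  p <- extract_parameters(smp$obs)
  expect_lt(abs(p$alpha - smp$truth$alpha) / smp$truth$alpha, 0.02)
  expect_equal(p$epsilon, smp$truth$epsilon_realized, tolerance = 1e-12)
})

test_that("Day 1 frame resolution and degenerate inputs raise errors", {
  m <- matrix(1, 2, 64)
  late <- tiled_observation("L", "A", 2000, c(48, 72), tile_counts = m)
  expect_error(adhesion_ratio(late), "Day 1")
  # within the +/- 3 h tolerance the nearest frame is accepted
  near <- tiled_observation("N", "A", 2000, c(26, 48), tile_counts = m)
  expect_equal(adhesion_ratio(near), 64 / (2.3409 * 2000))
  zero <- uniform_obs(per_tile = 0)
  expect_error(seeding_heterogeneity(zero), "undefined")
  totals <- tiled_observation("T", "A", 2000, c(24, 48),
                              total_counts = c(100, 200))
  expect_error(seeding_heterogeneity(totals), "tile-resolved")
  expect_error(max_cell_density(totals), "assume_uniform")
  expect_equal(max_cell_density(totals, assume_uniform = TRUE), 200 / 2.3409)
})

test_that("the imaged area supports square and circular readings", {
  m <- rbind(rep(50, 64), rep(50, 64))
  sq <- tiled_observation("s", "A", 2000, c(24, 48), tile_counts = m)
  expect_equal(sq$S, 2.3409)
  circ <- tiled_observation("c", "A", 2000, c(24, 48), tile_counts = m,
                            S = pi * (1.53 / 2)^2)
  expect_equal(circ$S, 1.8385, tolerance = 1e-4)
  expect_gt(adhesion_ratio(circ), adhesion_ratio(sq))
})

test_that("observations survive a CSV round trip", {
  set.seed(21)
  cfg <- generator_config(replicates = 1)
  exp_ <- generate_experiment(cfg, seed = 9, operators = "A")
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(exp_$observations, path)
  back <- read_observations(path)
  expect_setequal(names(back), names(exp_$observations))
  for (id in names(back)) {
    expect_equal(back[[id]]$tile_counts, exp_$observations[[id]]$tile_counts,
                 ignore_attr = TRUE)
    expect_equal(back[[id]]$times, exp_$observations[[id]]$times)
    expect_equal(back[[id]]$X_seed, exp_$observations[[id]]$X_seed)
  }
  # totals-only rows round-trip too
  tot <- list(T1 = tiled_observation("T1", "B", 1500, c(24, 48),
                                     total_counts = c(100, 250)))
  write_observations(tot, path)
  back2 <- read_observations(path)
  expect_null(back2$T1$tile_counts)
  expect_equal(back2$T1$total_counts, c(100, 250))
})
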