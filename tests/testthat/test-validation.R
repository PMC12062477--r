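test_that("experimental probability is the satisfied-sample fraction", {
  spec <- quality_spec()
  N <- rep(6e4, 12); P <- rep(0.5, 12)
  expect_equal(experimental_probability(N, P, spec), 100)
  P[1] <- 0.9
  expect_equal(experimental_probability(N, P, spec), 100 * 11 / 12)
  expect_equal(experimental_probability(N, P, spec), 91.6667,
               tolerance = 1e-4)
  expect_equal(experimental_probability(rep(1e3, 12), P, spec), 0)
  expect_error(experimental_probability(numeric(0), numeric(0), spec))
})

test_that("category assignment follows the h/h_exp crossing at pi", {
  expect_equal(as.character(categorize_condition(95, 92, 90)), "CDS")
  # inclusive at pi on the prediction side
  expect_equal(as.character(categorize_condition(90, 89.9, 90)), "IDS")
  expect_equal(as.character(categorize_condition(10, 95, 90)), "I_notDS")
  expect_equal(as.character(categorize_condition(10, 5, 90)), "C_notDS")
  expect_equal(as.character(categorize_condition(50, 90, 90)), "I_notDS")
  expect_error(categorize_condition(120, 50, 90), "must be in")
})

test_that("metrics reproduce the published category arithmetic", {
  cats <- factor(c(rep("CDS", 11), rep("IDS", 1), rep("I_notDS", 18),
                   rep("C_notDS", 69)),
                 levels = c("CDS", "C_notDS", "IDS", "I_notDS"))
  expect_length(cats, 99)
  m <- compute_metrics(cats)
  expect_equal(m$nCDS, 11); expect_equal(m$nIDS, 1)
  expect_equal(m$nI_notDS, 18); expect_equal(m$nC_notDS, 69)
  expect_equal(m$R1, 11 / 12, tolerance = 1e-12)
  expect_equal(m$R2, 11 / 29, tolerance = 1e-12)
  expect_equal(m$R3, 69 / 70, tolerance = 1e-12)
  expect_lt(abs(m$R1 - 0.917), 5e-4)
  expect_lt(abs(m$R2 - 0.379), 5e-4)
  expect_lt(abs(m$R3 - 0.986), 5e-4)
})

test_that("undefined ratios are reported missing, never 0 or 1", {
  # every condition experimentally feasible: R3's denominator vanishes
  all_feasible <- factor(c(rep("CDS", 5), rep("I_notDS", 4)),
                         levels = c("CDS", "C_notDS", "IDS", "I_notDS"))
  expect_warning(m <- compute_metrics(all_feasible), "R3")
  expect_true(is.na(m$R3))
  expect_equal(m$R1, 1); expect_equal(m$R2, 5 / 9)
  # empty design space: R1's denominator vanishes
  no_ds <- factor(rep(c("C_notDS", "I_notDS"), 3),
                  levels = c("CDS", "C_notDS", "IDS", "I_notDS"))
  expect_warning(m2 <- compute_metrics(no_ds), "R1")
  expect_true(is.na(m2$R1))
})

test_that("design-space validation partitions the validation grid", {
  fx <- pre_experiment_fixture()
  set.seed(61)
  val <- generate_experiment(generator_config(), seed = 301,
                             operators = c("B", "C"))
  g <- condition_grid()
  map <- probability_map(g, fx$pool, fx$interval, M = 300, seed = 41)
  ds <- determine_design_space(map, 90)
  conditions <- observations_to_conditions(val$observations, g$t_h_days)
  rep_ <- validate_design_space(ds, conditions)
  per <- rep_$conditions
  expect_equal(nrow(per), 99)
  expect_true(all(per$n == 12))
  m <- rep_$metrics
  expect_equal(m$nCDS + m$nC_notDS + m$nIDS + m$nI_notDS, 99)
  expect_true(all(per$h_exp >= 0 & per$h_exp <= 100))
})

test_that("off-grid validation conditions are rejected, not snapped", {
  fx <- pre_experiment_fixture()
  map <- probability_map(condition_grid(), fx$pool, fx$interval, M = 50,
                         seed = 1)
  ds <- determine_design_space(map, 90)
  bad <- data.frame(X_seed = 1600, t_h_days = 5, N_exp = 6e4, P_exp = 0.5)
  expect_error(validate_design_space(ds, bad), "no snapping")
})

test_that("per-sample and global confluency denominators both work", {
  set.seed(71)
  val <- generate_experiment(generator_config(replicates = 2), seed = 303,
                             operators = "B")
  per <- observations_to_conditions(val$observations, c(5, 9))
  glob <- observations_to_conditions(val$observations, c(5, 9),
                                     X_m_mode = "global")
  expect_equal(per$N_exp, glob$N_exp)
  expect_false(isTRUE(all.equal(per$P_exp, glob$P_exp)))
  # a shared denominator makes confluency rank exactly with the cell number
  at9 <- glob$t_h_days == 9
  expect_equal(order(glob$P_exp[at9]), order(glob$N_exp[at9]))
})

test_that("permutation study is stable across exchangeable groups", {
  cfg <- generator_config(replicates = 3)
  exp_ <- generate_experiment(cfg, seed = 99)
  groups <- split_by_operator(exp_)
  out <- suppressWarnings(
    permutation_study(groups, pis = c(50, 90), M = 200, seed = 7))
  expect_equal(nrow(out), 6)   # 3 pre-experiments x 2 risk levels
  # within each permutation the DS shrinks as pi rises
  for (p in unique(out$pre)) {
    sub <- out[out$pre == p, ]
    expect_lte(sub$ds_size[sub$pi == 90], sub$ds_size[sub$pi == 50])
  }
  # exchangeable groups: headline metrics vary little across permutations
  r3 <- out$R3[out$pi == 90]
  expect_lt(diff(range(r3)), 0.2)
  # an empty DS is reported as zero conditions with missing R1
  sub90 <- out[out$pi == 90 & out$ds_size == 0, ]
  if (nrow(sub90)) expect_true(all(is.na(sub90$R1)))
})
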