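test_that("generators are pure functions of their config, seed included", {
  cfg <- sim_config("neutral_drift", t_generations = 500, n_bins = 8,
                    n_per_bin = 12, within_cv = 0.1, seed = 42)
  expect_identical(simulate_mean_trajectory(cfg), simulate_mean_trajectory(cfg))
  s1 <- simulate_lineage_series(cfg)
  s2 <- simulate_lineage_series(cfg)
  expect_identical(s1$bins, s2$bins)
  cfg_b <- sim_config("neutral_drift", t_generations = 500, n_bins = 8,
                      n_per_bin = 12, within_cv = 0.1, seed = 43)
  expect_false(identical(simulate_lineage_series(cfg_b)$bins, s1$bins))
})

test_that("a zero-generation config yields a length-1 path at the start value", {
  cfg <- sim_config("neutral_drift", t_generations = 0, n_bins = 1,
                    start_mean = 900, seed = 1)
  path <- simulate_mean_trajectory(cfg)
  expect_equal(path, log(900))
})

test_that("drift-free directional change is exactly e * beta * t on the log scale", {
  cfg <- sim_config("directional", params = population_params(0.009, Inf, 29),
                    beta = 0.001, t_generations = 1e4, n_bins = 2, seed = 1)
  path <- simulate_mean_trajectory(cfg)
  expect_equal(path[length(path)] - path[1], 0.009 * 0.001 * 1e4)
})

test_that("neutral-drift replicate variance matches the drift null moment e t / Ne", {
  pp <- population_params(0.009, 5000, 29)
  finals <- vapply(1:2000, function(i) {
    cfg <- sim_config("neutral_drift", params = pp, t_generations = 1e4,
                      n_bins = 2, seed = i)
    path <- simulate_mean_trajectory(cfg)
    path[length(path)] - path[1]
  }, numeric(1))
  target <- drift_null_variance(pp, 1e4)  # 0.018
  expect_lt(abs(var(finals) - target) / target, 0.1)
  expect_lt(abs(mean(finals)), 3 * sqrt(target / 2000))
})

test_that("mutation-drift replicate variance matches factor * sigma2_m * t", {
  mp <- mutation_params(4e-6, 2)
  finals <- vapply(1:1500, function(i) {
    cfg <- sim_config("mutation_drift", mut = mp, t_generations = 2000,
                      n_bins = 2, seed = 6000 + i)
    path <- simulate_mean_trajectory(cfg)
    path[length(path)] - path[1]
  }, numeric(1))
  target <- mutation_drift_null_variance(mp, 2000)
  expect_lt(abs(var(finals) - target) / target, 0.12)
})

test_that("noise-free sampling reproduces the trajectory exactly", {
  cfg <- sim_config("neutral_drift", t_generations = 1000, n_bins = 5,
                    n_per_bin = 4, within_cv = 0, measurement_cv = 0,
                    dimorphism_ratio = 1, seed = 8)
  path <- simulate_mean_trajectory(cfg)
  series <- sample_fossil_series(path, cfg)
  expect_equal(series$bins$sd, rep(0, 5))
  idx <- length(path) - series$bins$age
  expect_equal(series$bins$mean, exp(path[idx]))
})

test_that("large bins recover the within-population CV", {
  cfg <- sim_config("stasis", t_generations = 10, n_bins = 2, n_per_bin = 1e4,
                    within_cv = 0.10, dimorphism_ratio = 1, stasis_sd = 0,
                    seed = 9)
  series <- simulate_lineage_series(cfg)
  bin_cv <- series$bins$sd / series$bins$mean
  expect_true(all(abs(bin_cv - 0.10) / 0.10 < 0.05))
})

test_that("single-specimen bins carry a missing SD", {
  cfg <- sim_config("stasis", t_generations = 100, n_bins = 3, n_per_bin = 1,
                    within_cv = 0.1, seed = 10)
  series <- simulate_lineage_series(cfg)
  expect_true(all(is.na(series$bins$sd)))
  expect_equal(series$bins$n, rep(1, 3))
})

test_that("species table bookkeeping: two sex rows per species plus a truth row", {
  sim <- simulate_species_cv_table(n_species = 48, seed = 3)
  expect_equal(nrow(sim$table), 96L)
  expect_equal(nrow(sim$truth), 48L)
  expect_setequal(unique(sim$table$sex), c("female", "male"))
  expect_error(simulate_species_cv_table(n_species = 1), "n_species")
})

test_that("estimated pooled within-sex CVs track the generating truth at large n", {
  sim <- simulate_species_cv_table(n_species = 48, n_range = c(1000, 1000),
                                   seed = 12)
  est <- species_cvs(sim$table, "within_sex")
  truth <- sim$truth$true_cv[match(names(est), sim$truth$species)]
  expect_gt(cor(est, truth), 0.95)
})

test_that("invalid configs are rejected with field-level messages", {
  expect_error(sim_config("neutral_drift", t_generations = 5, n_bins = 10),
               "t_generations")
  expect_error(sim_config("neutral_drift", within_cv = 1.2), "within_cv")
  expect_error(sim_config("neutral_drift", dimorphism_ratio = 0), "dimorphism")
})
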