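test_that("identical seed and config give bit-identical output", {
  a <- simulate_experiment(sim_config(seed = 42))
  b <- simulate_experiment(sim_config(seed = 42))
  expect_identical(a, b)
  c2 <- simulate_experiment(sim_config(seed = 43))
  expect_false(identical(a$plants, c2$plants))
})

test_that("zero-noise plants satisfy the fractionation relation and mass balance exactly", {
  sim <- simulate_experiment(sim_config(seed = 7, noise_delta_2sd = 0,
                                        noise_conc_rel = 0))
  d <- derive_plants(sim$plants)
  tt <- sim$truth$per_plant
  cfg <- sim$truth$parameters
  # organ masses reconstruct the generating totals and compositions
  expect_equal(d$total_cd_ug, tt$total_cd_ug, tolerance = 1e-10)
  expect_equal(d$delta_tot, tt$delta_tot, tolerance = 1e-10)
  # the leaf obeys Delta_leaf-tot = epsilon * ln f_leaf
  expect_equal(d$d_l_tot, cfg$epsilon_seq_mob * log(d$f_leaf),
               tolerance = 1e-10)
  # leaf-stem offset is the configured target
  expect_equal(d$d_ls, rep(cfg$d_ls_target, nrow(d)), tolerance = 1e-10)
  # fit recovers the generating epsilon exactly
  fit <- fit_rayleigh(d$f_leaf, d$d_l_tot, "leaf")
  expect_equal(fit$epsilon, cfg$epsilon_seq_mob, tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-12)
  # reservoir bookkeeping: removed Cd equals the summed plant totals, and the
  # solution/product pair balances to the source composition
  by_tr <- rowsum(tt$total_cd_ug, tt$treatment_id)
  expect_equal(sim$solutions$cd_removed_ug, as.numeric(by_tr), tolerance = 1e-9)
  bal <- sim$solutions$f_remaining * sim$solutions$delta_final +
    (1 - sim$solutions$f_remaining) * tt$delta_tot[!duplicated(tt$treatment_id)]
  expect_equal(bal, rep(cfg$delta_init, nrow(sim$solutions)), tolerance = 1e-10)
})

test_that("default conditions land in the observed uptake and partitioning ranges", {
  sims <- lapply(1:20, function(s) simulate_experiment(sim_config(seed = s)))
  mean_total <- mean(vapply(sims, function(s) mean(s$truth$per_plant$total_cd_ug),
                            numeric(1)))
  # reservoir 6750 ug, mean uptake 5% over three plants: ~112 ug per plant
  expect_equal(mean_total, 6750 * 0.05 / 3, tolerance = 0.05)
  # uptake per treatment stays within the observed few-percent envelope
  upt <- unlist(lapply(sims, function(s) 1 - s$solutions$f_remaining))
  expect_true(all(upt > 0.02 & upt < 0.09))
  # structural Fe grouping (before measurement noise): Fe-present plants
  # exceed 100 ug total Cd and 100% TF, Fe-absent fall below
  d <- dplyr::bind_rows(lapply(6:10, function(s) derive_plants(
    simulate_experiment(sim_config(seed = s, noise_delta_2sd = 0,
                                   noise_conc_rel = 0))$plants)))
  expect_true(all(d$total_cd_ug[d$hydro_fe] > 100))
  expect_true(all(d$total_cd_ug[!d$hydro_fe] < 100))
  expect_true(all(d$tf_percent[d$hydro_fe] > 100))
  expect_true(all(d$tf_percent[!d$hydro_fe] < 100))
})

test_that("stronger sequestration fractionation increases the leaf-total offset", {
  base <- list(seed = 11, noise_delta_2sd = 0, noise_conc_rel = 0)
  d1 <- derive_plants(simulate_experiment(
    do.call(sim_config, c(base, epsilon_seq_mob = -0.13)))$plants)
  d2 <- derive_plants(simulate_experiment(
    do.call(sim_config, c(base, epsilon_seq_mob = -0.26)))$plants)
  # same seed, same f_leaf draws: doubling |epsilon| doubles Delta_leaf-tot
  expect_equal(d1$f_leaf, d2$f_leaf, tolerance = 1e-12)
  expect_true(all(d2$d_l_tot > d1$d_l_tot))
  expect_equal(d2$d_l_tot, 2 * d1$d_l_tot, tolerance = 1e-10)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(f_leaf_base = 0.1, fe_fshoot_shift = 0.17), "")
  expect_error(simulate_experiment(sim_config(seed = 1,
                                              base_uptake_fraction = 0.9)),
               "reservoir")
})
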