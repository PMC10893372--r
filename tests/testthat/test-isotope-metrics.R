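test_that("delta/ratio conversion is exact and invertible", {
  expect_equal(delta_from_ratio(2.3, 2.3), 0)
  expect_equal(delta_from_ratio(2.3 * 1.001, 2.3), 1.0)
  expect_error(delta_from_ratio(-1, 2.3), "positive")
  set.seed(11)
  r <- runif(50, 0.5, 3)
  expect_equal(ratio_from_delta(delta_from_ratio(r, 2.30024), 2.30024), r,
               tolerance = 1e-14)
})

test_that("capital delta is antisymmetric and propagates uncertainty in quadrature", {
  expect_equal(capital_delta(-0.67, -0.36), -0.31)
  expect_equal(capital_delta(0.123, 0.123), 0)
  expect_equal(capital_delta(0.4, -0.2), -capital_delta(-0.2, 0.4))
  cd <- capital_delta(delta_value(-0.67, 0.04), delta_value(-0.36, 0.04))
  expect_equal(cd$value, -0.31)
  expect_equal(cd$two_sd, sqrt(2) * 0.04)
})

test_that("inverse-variance weighting follows 1/sigma^2 with 2sd bookkeeping", {
  # hand arithmetic: sigmas 0.05 and 0.1 give 4:1 weights
  m <- ivw_mean(list(delta_value(0.0, 0.1), delta_value(0.5, 0.2)))
  expect_equal(m$value, 0.1)
  expect_equal(m$two_sd, 2 / sqrt(1 / 0.05^2 + 1 / 0.1^2))
  # equal uncertainties reduce to the arithmetic mean
  eq <- ivw_mean(list(delta_value(-0.7, 0.08), delta_value(-0.5, 0.08)))
  expect_equal(eq$value, -0.6)
  # invariant to uniform sigma rescaling
  sc <- ivw_mean(list(delta_value(0.0, 0.3), delta_value(0.5, 0.6)))
  expect_equal(sc$value, 0.1)
  # single value is its own mean
  expect_equal(ivw_mean(list(delta_value(-0.64, 0.04)))$value, -0.64)
  # missing sigma falls back to equal weights, flagged
  fb <- ivw_mean(list(delta_value(0, NA), delta_value(1, 0.1)))
  expect_equal(fb$value, 0.5)
  expect_true(attr(fb, "equal_weights"))
  expect_error(ivw_mean(list()), "empty")
})

test_that("organ Cd mass is concentration times biomass in micrograms", {
  expect_equal(organ_cd_mass(322, 0.10), 32.2)
  expect_equal(organ_cd_mass(0, 0.5), 0)
})

test_that("plant totals conserve mass and weight the total delta by Cd mass", {
  organs <- tibble::tibble(
    organ = c("leaf", "stem", "root"),
    dry_mass_g = c(0.5, 0.3, 0.2),
    conc_mg_per_kg = c(100, 100, 200),  # 50, 30, 40 ug
    delta114_permil = c(-0.40, -0.70, -0.70),
    two_sd_permil = c(0.05, 0.05, 0.05)
  )
  pt <- plant_totals(organs)
  expect_equal(pt$total_cd_ug, 120)
  expect_equal(pt$cd_leaf_ug + pt$cd_stem_ug + pt$cd_root_ug, pt$total_cd_ug,
               tolerance = 1e-12)
  expect_equal(pt$delta_tot, (50 * -0.40 + 70 * -0.70) / 120)
  expect_equal(pt$f_shoot, 2 / 3)
  expect_equal(pt$f_leaf + pt$f_stem + pt$f_root, 1, tolerance = 1e-12)
  expect_equal(pt$tf_percent, 200)

  # single organ: its own delta, fraction 1
  one <- plant_totals(organs[1, ])
  expect_equal(one$delta_tot, -0.40)
  expect_equal(one$f_leaf, 1)
  expect_false(one$complete)

  # two organs with equal Cd mass: midpoint delta
  two <- plant_totals(tibble::tibble(
    organ = c("leaf", "root"), dry_mass_g = c(0.1, 0.1),
    conc_mg_per_kg = c(100, 100), delta114_permil = c(-0.5, -0.7)))
  expect_equal(two$delta_tot, -0.6)

  expect_error(plant_totals(organs[c(1, 1), ]), "duplicated")
})

test_that("translocation factor handles the 100% boundary and degenerate root", {
  expect_equal(translocation_factor(50, 30, 40), 200)
  expect_equal(translocation_factor(0, 0, 40), 0)
  expect_equal(translocation_factor(25, 15, 40), 100)  # shoot equals root
  expect_error(translocation_factor(10, 10, 0), "root")
})

test_that("derive_plants agrees with plant_totals on every plant", {
  d <- derived_from_seed(3)
  sim <- simulate_experiment(sim_config(seed = 3))
  pl <- sim$plants[sim$plants$analysed, ]
  for (i in seq_len(nrow(d))) {
    sub <- pl[pl$treatment_id == d$treatment_id[i] &
                pl$replicate_id == d$replicate_id[i], ]
    pt <- plant_totals(sub)
    expect_equal(d$total_cd_ug[i], pt$total_cd_ug)
    expect_equal(d$delta_tot[i], pt$delta_tot)
    expect_equal(d$f_shoot[i], pt$f_shoot)
    expect_equal(d$tf_percent[i], pt$tf_percent)
  }
})

test_that("within-plant Delta algebra is additive: L-R = L-S + S-R", {
  d <- derived_from_seed(5)
  expect_equal(d$d_lr, d$d_ls + d$d_sr, tolerance = 1e-12)
})

test_that("treatment summary of a single plant equals the per-plant values", {
  sim <- simulate_experiment(sim_config(seed = 9, replicates_grown = 1,
                                        replicates_analysed = 1))
  s <- treatment_summary(sim$plants)
  d <- derive_plants(sim$plants)
  expect_equal(s$n_plants, rep(1L, nrow(s)))
  expect_equal(s$delta_tot, d$delta_tot[order(d$treatment_id)])
  expect_equal(s$d_l_tot, d$d_l_tot[order(d$treatment_id)])
  expect_equal(s$tf_percent, d$tf_percent[order(d$treatment_id)])
})

test_that("treatment summary averages deltas by inverse variance across replicates", {
  # two plants, same organs, different uncertainties on the root delta
  pl <- tibble::tibble(
    treatment_id = 1, replicate_id = rep(1:2, each = 3),
    hydro_fe = TRUE, hydro_zn = TRUE, foliar_fe = FALSE, foliar_zn = FALSE,
    organ = rep(c("root", "stem", "leaf"), 2),
    dry_mass_g = rep(c(0.1, 0.2, 0.5), 2),
    conc_mg_per_kg = rep(c(300, 200, 100), 2),
    delta114_permil = c(-0.8, -0.7, -0.5, -0.6, -0.7, -0.5),
    two_sd_permil = c(0.05, 0.05, 0.05, 0.10, 0.05, 0.05)
  )
  s <- treatment_summary(pl)
  w <- 1 / (c(0.05, 0.10) / 2)^2
  expect_equal(s$delta_root, sum(w * c(-0.8, -0.6)) / sum(w))
  expect_equal(s$d_sr, mean(c(-0.7 - -0.8, -0.7 - -0.6)))  # arithmetic
  expect_error(treatment_summary(pl[0, ]), "")
})

test_that("final solution state is an exact two-pool mass balance", {
  # no uptake
  st0 <- final_solution_state(-0.36, 6750, numeric(0), numeric(0))
  expect_equal(st0$f_remaining, 1)
  expect_equal(st0$delta_final, -0.36)
  # 5% uptake at -0.635: closed-form value
  st <- final_solution_state(-0.36, 6750, plant_cd_ug = 337.5,
                             plant_delta = -0.635)
  expect_equal(st$f_remaining, 0.95)
  expect_equal(st$delta_final, (-0.36 + 0.05 * 0.635) / 0.95)
  expect_equal(st$delta_final, -0.3455, tolerance = 1e-3)
  # identity f*d_final + (1-f)*d_plants = d_init for random inputs
  set.seed(21)
  for (i in 1:20) {
    cd <- runif(3, 10, 200)
    dl <- runif(3, -1, 0)
    s <- final_solution_state(-0.36, 6750, cd, dl)
    expect_equal(s$f_remaining * s$delta_final +
                   (1 - s$f_remaining) * s$delta_plants_weighted,
                 -0.36, tolerance = 1e-12)
  }
  expect_error(final_solution_state(-0.36, 100, 150, -0.6), "mass-balance")
})

test_that("micromolar/mass concentration conversions are mutually inverse", {
  x <- mg_to_umol_per_l(umol_to_mg_per_l(20, element_molar_mass("Cd")),
                        element_molar_mass("Cd"))
  expect_equal(x, 20, tolerance = 1e-14)
  expect_error(element_molar_mass("Pb"), "unknown")
})
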