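test_that("forward model reproduces the end-members and the p = 0.5 blend", {
  sys <- test_system()
  expect_equal(forward_mix(0, 0, 0, sys), sys$reference_ratios)
  expect_equal(forward_mix(1, 0.5, 0, sys), sys$spike_ratios)  # alpha acts on natural only
  expect_equal(forward_mix(0.5, 0, 0, sys),
               0.5 * sys$spike_ratios + 0.5 * sys$reference_ratios)
  expect_error(forward_mix(1.2, 0, 0, sys), "p must lie")
  expect_error(isotope_system(c(1, 1, 1), c(1, 1, 1.5)), "singular")
})

test_that("inversion round-trips the forward model", {
  sys <- test_system()
  # null fractionation
  inv0 <- invert_double_spike(forward_mix(0.5, 0, 0, sys), sys)
  expect_true(inv0$converged)
  expect_equal(c(inv0$p, inv0$alpha, inv0$beta), c(0.5, 0, 0), tolerance = 1e-10)
  # alpha chosen so the natural composition sits at -0.64 permil
  g114 <- sys$isotope_masses[4] / sys$isotope_masses[1]
  alpha <- log(1 - 0.64e-3) / log(g114)
  inv <- invert_double_spike(forward_mix(0.6, alpha, 1.5, sys), sys)
  expect_true(inv$converged)
  expect_equal(inv$delta114_permil, -0.64, tolerance = 1e-6)
  expect_equal(inv$p, 0.6, tolerance = 1e-8)
  expect_equal(inv$beta, 1.5, tolerance = 1e-8)
})

test_that("inversion recovers a random grid of mixtures", {
  sys <- test_system()
  set.seed(101)
  n_ok <- 0L
  for (i in 1:100) {
    th <- c(runif(1, 0.3, 0.7), runif(1, -2e-4, 2e-4), runif(1, -2, 2))
    inv <- invert_double_spike(forward_mix(th[1], th[2], th[3], sys), sys)
    ok <- inv$converged &&
      all(abs(c(inv$p, inv$alpha, inv$beta) - th) < 1e-8) &&
      inv$residual < 1e-12
    n_ok <- n_ok + ok
    # delta from alpha is untouched by p and beta (permil-scale agreement)
    expect_lt(abs(inv$delta114_permil - delta114_from_alpha(th[2], sys)), 1e-6)
  }
  expect_equal(n_ok, 100L)
})

test_that("analytic Jacobian matches central finite differences", {
  sys <- test_system()
  th <- c(0.43, 1.2e-4, -0.8)
  J <- cdisoflux:::.ds_jacobian(th[1], th[2], th[3], sys)
  h <- 1e-6
  for (k in 1:3) {
    up <- dn <- th
    up[k] <- th[k] + h; dn[k] <- th[k] - h
    fd <- (cdisoflux:::forward_mix_unchecked(up[1], up[2], up[3], sys) -
             cdisoflux:::forward_mix_unchecked(dn[1], dn[2], dn[3], sys)) / (2 * h)
    expect_equal(J[, k], fd, tolerance = 1e-6)
  }
})

test_that("isotope dilution recovers a known concentration through the full chain", {
  sys <- test_system()
  nat_ng <- 322 * 0.04 * 1000  # 322 mg/kg in a 0.04 g digest
  spike_ng <- 1.5 * nat_ng
  measured <- mix_ratios_oracle(nat_ng, spike_ng, sys, alpha = -1.5e-2, beta = 1.0)
  inv <- invert_double_spike(measured, sys)
  expect_true(inv$converged)
  id <- isotope_dilution_conc(inv, spike_cd_ng = spike_ng,
                              sample_dry_mass_g = 0.04, system = sys)
  expect_equal(id$conc_mg_per_kg, 322, tolerance = 1e-3)  # within 0.1%
  expect_equal(id$natural_cd_ng, nat_ng, tolerance = 1e-3)
})

test_that("equal-composition spike and natural balance exactly at p = 0.5", {
  sys <- symmetric_system()
  id <- isotope_dilution_conc(0.5, spike_cd_ng = 250, sample_dry_mass_g = 0.04,
                              system = sys)
  expect_equal(id$natural_cd_ng, 250, tolerance = 1e-10)
})

test_that("concentration falls monotonically to zero as p approaches 1", {
  sys <- test_system()
  ps <- c(0.5, 0.7, 0.9, 0.99, 0.999)
  conc <- vapply(ps, function(p) {
    isotope_dilution_conc(p, spike_cd_ng = 250, sample_dry_mass_g = 0.04,
                          system = sys)$conc_mg_per_kg
  }, numeric(1))
  expect_true(all(diff(conc) < 0))
  expect_warning(id1 <- isotope_dilution_conc(1, spike_cd_ng = 250,
                                              sample_dry_mass_g = 0.04,
                                              system = sys), "no natural")
  expect_equal(id1$conc_mg_per_kg, 0)
  expect_error(isotope_dilution_conc(0, spike_cd_ng = 250,
                                     sample_dry_mass_g = 0.04, system = sys),
               "no spike")
})

test_that("spike planning honours the ratio and total windows jointly", {
  ok <- plan_spike(100, c(1, 2), c(200, 300))
  expect_true(ok$feasible)
  expect_true(ok$spike_range_ng[1] >= 100 && ok$spike_range_ng[2] <= 200)
  expect_true(ok$spike_cd_ng >= 100 && ok$spike_cd_ng <= 200)
  expect_true(ok$expected_total_ng >= 200 && ok$expected_total_ng <= 300)
  bad <- plan_spike(300, c(1, 2), c(200, 300))  # minimum total is 600
  expect_false(bad$feasible)
  expect_true(is.na(bad$spike_cd_ng))
  expect_error(plan_spike(0), "> 0")
})

test_that("batch reduction reproduces per-sample inversions and concentrations", {
  sys <- test_system()
  set.seed(77)
  nat <- runif(4, 5000, 20000)
  spk <- nat * runif(4, 1, 2)
  dm <- runif(4, 0.02, 0.08)
  tab <- do.call(rbind, lapply(1:4, function(i) {
    m <- mix_ratios_oracle(nat[i], spk[i], sys, alpha = -2e-2, beta = 0.6)
    data.frame(sample_id = paste0("s", i), r111_110 = m[1], r113_110 = m[2],
               r114_110 = m[3], spike_mass_g = spk[i] / sys$spike_conc_ng_g,
               sample_dry_mass_g = dm[i])
  }))
  out <- reduce_spiked_ratios(tab, sys)
  expect_true(all(out$converged))
  expect_equal(out$conc_mg_per_kg, nat / dm / 1000, tolerance = 1e-3)
  expect_equal(out$delta114_permil,
               rep(delta114_from_alpha(-2e-2, sys), 4), tolerance = 1e-6)
})

test_that("packaged placeholder system loads and is invertible", {
  sys <- default_isotope_system()
  inv <- invert_double_spike(forward_mix(0.55, 0, 0.3, sys), sys)
  expect_true(inv$converged)
  expect_equal(inv$p, 0.55, tolerance = 1e-8)
})
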