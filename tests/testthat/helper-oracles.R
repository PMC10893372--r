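# Self-consistent synthetic isotope system for double-spike tests; the values
# are arbitrary but physically shaped (natural-like reference, 111/113-heavy
# spike) and claim nothing about real certified compositions.
test_system <- function() {
  isotope_system(reference_ratios = c(1.02, 0.98, 2.30),
                 spike_ratios = c(50, 45, 3),
                 spike_conc_ng_g = 100)
}

# A system in which reference and spike share the same 110Cd atom fraction and
# the same mean atomic mass, so that at p = 0.5 equal masses of natural and
# spike Cd are present. Built by solving the two matching constraints for the
# spike's 111/110 and 113/110 ratios at a chosen 114/110.
symmetric_system <- function() {
  m <- c(109.9030021, 110.9041781, 112.9044017, 113.9033585)
  ref <- c(1.02, 0.98, 2.30)
  c114 <- 1.0
  s_target <- sum(ref * m[2:4]) - c114 * m[4]
  b <- (s_target - (sum(ref) - c114) * m[2]) / (m[3] - m[2])
  a <- sum(ref) - c114 - b
  isotope_system(reference_ratios = ref, spike_ratios = c(a, b, c114))
}

# Measured-ratio oracle by direct mole bookkeeping: convert natural and spike
# Cd masses to isotope moles via abundances and mean atomic masses, add, take
# ratios, apply instrumental bias. Independent of forward_mix's p-based mixing.
mix_ratios_oracle <- function(nat_ng, spike_ng, sys, alpha = 0, beta = 0) {
  m <- sys$isotope_masses
  g <- m[2:4] / m[1]
  nat_r <- c(1, sys$reference_ratios * g^alpha)
  spk_r <- c(1, sys$spike_ratios)
  nat_ab <- nat_r / sum(nat_r)
  spk_ab <- spk_r / sum(spk_r)
  nat_mol <- nat_ng / sum(nat_ab * m)
  spk_mol <- spike_ng / sum(spk_ab * m)
  mix <- nat_mol * nat_ab + spk_mol * spk_ab
  (mix[2:4] / mix[1]) * g^beta
}

# Rank-formula Kruskal-Wallis H with tie correction, written from the textbook
# definition (no call into the package or into kruskal.test).
kw_h_oracle <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- vapply(groups, length, integer(1))
  g <- rep(seq_along(groups), sizes)
  rs <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Brute-force exact permutation p-value for two groups: enumerate every
# assignment of the pooled values to the first group.
kw_exact_oracle_2g <- function(g1, g2) {
  x <- c(g1, g2)
  n1 <- length(g1)
  h_obs <- kw_h_oracle(list(g1, g2))
  picks <- utils::combn(length(x), n1, simplify = FALSE)
  hs <- vapply(picks, function(ix) kw_h_oracle(list(x[ix], x[-ix])), numeric(1))
  mean(hs >= h_obs - 1e-12)
}

# One simulated experiment reduced to the analysed plants' derived table.
derived_from_seed <- function(seed, ...) {
  sim <- simulate_experiment(sim_config(seed = seed, ...))
  derive_plants(sim$plants[sim$plants$analysed, ])
}

# printed-precision comparison: equal to within half a unit in the last
# printed decimal place
expect_printed <- function(actual, printed, digits) {
  expect_true(all(abs(actual - printed) <= 0.5 * 10^(-digits) + 1e-12),
              label = sprintf("%s vs printed %s", toString(round(actual, 6)),
                              toString(printed)))
}
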