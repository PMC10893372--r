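# cdisoflux

Cadmium isotope mass balance and Rayleigh fractionation analysis for
hydroponic plant experiments.

## The problem

Cadmium accumulates in food crops such as cacao, and one mitigation idea is to
manipulate the supply of essential metals (Fe, Zn) that compete with Cd for
uptake and transport. Closed hydroponic experiments make whole-system Cd
inventories measurable: every microgram of Cd in roots, stems and leaves came
from a finite, well-characterised solution reservoir. Natural-abundance Cd
stable isotope ratios (reported as δ¹¹⁴Cd, the permil deviation of
¹¹⁴Cd/¹¹⁰Cd from a reference standard) add a second, process-sensitive
dimension: root uptake prefers light isotopes, and root sequestration versus
shoot mobilisation fractionates Cd further inside the plant.

`cdisoflux` implements the full data-reduction and analysis chain for such
experiments, for analysts working with per-organ dry biomass, Cd
concentrations and δ¹¹⁴Cd values (and optionally the raw spiked MC-ICP-MS
ratio measurements upstream of them):

- **Double-spike reduction** — exponential-law inversion of measured
  (¹¹¹Cd/¹¹⁰Cd, ¹¹³Cd/¹¹⁰Cd, ¹¹⁴Cd/¹¹⁰Cd) triples for the spike proportion
  *p*, the natural fractionation exponent α and the instrumental exponent β
  (damped Newton, analytic Jacobian), isotope-dilution concentrations from
  *p*, and spike-addition planning.
- **Mass balance** — organ Cd masses, Cd-mass-weighted total-plant δ¹¹⁴Cd,
  partition fractions *f*, translocation factors
  TF(%) = (Cd_leaf + Cd_stem)/Cd_root × 100, apparent fractionations
  Δ¹¹⁴Cd_A−B = δ_A − δ_B, inverse-variance replicate averaging, and exact
  two-pool bookkeeping of the solution reservoir.
- **Rayleigh fractionation** — the uptake fractionation factor
  ε_uptake = (δ_final − δ_init)/ln *f* from reservoir evolution, the
  within-plant sequestration/mobilisation factor from
  δ_mob = δ_tot + ε_seq-mob · ln *f*_mob, and a pooled least-squares fit of
  Δ_sink-tot against ln *f*_sink forced through (f = 1, Δ = 0).
- **Group statistics** — Kruskal–Wallis comparisons of pooled design groups,
  with exact permutation p-values at small n.
- **Synthetic experiments** — a generator that emulates the whole design
  (finite reservoir, Fe-dependent uptake and partitioning, exact fractionation
  structure before noise) with known ground truth, so every stage is testable.

## Worked example

Simulate one eight-treatment experiment (two analysed replicates per
treatment), run the pipeline, and inspect the fractionation estimates:

```r
library(cdisoflux)

sim <- simulate_experiment(sim_config(seed = 1))
res <- run_pipeline(sim$plants[sim$plants$analysed, ])

res$rayleigh$leaf
#> Rayleigh fit (leaf sink, forced through Delta = 0 at f = 1)
#>   epsilon = -0.1351 permil (|epsilon| = 0.1351), n = 16, residual sd = 0.0280 permil

mean(abs(res$solutions$epsilon_uptake))
#> [1] 0.286

res$stats[["total_cd_ug by hydro_fe"]]
#> Kruskal-Wallis: H = 10.5882 (df = 1), p = 0.001138 [chi-square approximation; n = 10+6]
#>   variable total_cd_ug by hydro_fe
```

The leaf-sink fit recovers the generating sequestration/mobilisation factor
(−0.13‰) within the analytical noise; the mean uptake fractionation magnitude
(0.286‰) sits at the value implied by ~5% uptake of an initially −0.36‰
reservoir; and the planted hydroponic-Fe effect on total plant Cd is detected
(p ≈ 0.001).

The published per-treatment tables ship with the package, so the same
estimators run on the real study's printed values:

```r
t2 <- cacao_table2()
fit_rayleigh(exp(t2$d_l_tot / t2$eps_seq_mob), t2$d_l_tot, sink = "leaf")
#> Rayleigh fit (leaf sink, forced through Delta = 0 at f = 1)
#>   epsilon = -0.1249 permil (|epsilon| = 0.1249), n = 8, residual sd = 0.0281 permil
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/cdisoflux.R` (`simulate`, `reduce`, `run` subcommands).

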