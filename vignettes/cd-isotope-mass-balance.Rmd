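---
title: "Cadmium isotope mass balance and Rayleigh fractionation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cadmium isotope mass balance and Rayleigh fractionation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdisoflux)
```

# Scope and model

`cdisoflux` analyses closed-system hydroponic experiments in which plants grow
in a finite Cd reservoir of known mass and isotope composition. Three nested
mass balances carry the analysis:

1. **Organ to plant.** Organ Cd masses are concentration (mg/kg dry weight)
   times dry biomass (g), in µg. The total-plant δ¹¹⁴Cd is the Cd-mass-weighted
   mean of the organ values; partition fractions *f*_organ and the
   translocation factor TF(%) = (Cd_leaf + Cd_stem)/Cd_root · 100 follow
   directly. These identities are exact and the package asserts them to
   numerical precision rather than estimating them.

2. **Plant to reservoir.** With fraction *f* of the reservoir Cd left,
   *f*·δ_final + (1 − *f*)·δ_plants = δ_init exactly. `final_solution_state()`
   solves this for δ_final; `uptake_epsilon()` then gives the uptake
   fractionation factor ε = (δ_final − δ_init)/ln *f*. At the few-percent
   uptake typical of such designs, the apparent plant–solution fractionation
   Δ_tot-sol and ε differ by less than the analytical precision (the
   accumulated-product algebra in `accumulated_product_delta()` quantifies
   this reservoir effect exactly).

3. **Within plant.** Sequestration of isotopically light Cd in roots with
   unidirectional mobilisation of heavier Cd to a sink (leaves or shoots) is
   modelled as closed-system Rayleigh fractionation:
   δ_sink = δ_tot + ε_seq-mob · ln *f*_sink. `fit_rayleigh()` pools plants by
   least squares of Δ_sink-tot on ln *f*_sink with the line forced through
   (f = 1, Δ = 0), because a sink containing all of the plant's Cd cannot be
   fractionated from it. The relation is applied in this printed,
   instantaneous form to the accumulated sink pool — matching how such fits
   are reported in the plant-isotope literature — rather than in the exact
   accumulated-product form, which remains available separately for
   sensitivity checks.

Sign conventions: a sink isotopically heavier than the source (positive
Δ_sink-tot) at *f* < 1 forces ε < 0 in both estimators. ε values are stored
signed; reports often quote magnitudes, and both are printed.

## Assumptions

- The reservoir is well mixed and closed; adsorption to root surfaces is
  neglected in the solution mass balance (defensible at ~5% uptake, and noted
  as an assumption of the underlying study design).
- Uptake is treated as a single Rayleigh step between the initial and final
  solution states; no time resolution is attempted because the fractionation
  factor is defined only on those two states.
- Within a plant, the mobilised pool is a single sink; multi-compartment
  transport models are out of scope.

# Double-spike reduction

Raw spiked MC-ICP-MS measurements are reduced with the exponential
mass-fractionation law for both natural and instrumental fractionation, the
standard choice for this instrument class. With mass ratios
g_i = m_i/m₁₁₀, the forward model for the measured ratio triple is

measured_i = (p·S_i + (1 − p)·R_i·g_i^α) · g_i^β,

where R and S are the reference and spike ratio sets, p is the molar fraction
of ¹¹⁰Cd-basis Cd from the spike, α the natural and β the instrumental
exponent. The natural composition is δ¹¹⁴Cd = (g₁₁₄^α − 1)·1000.
`invert_double_spike()` solves the three equations by damped Newton iteration
(analytic Jacobian, step halving until the residual norm decreases, relative
residual tolerance 1e-12, at most 100 iterations, default start (0.5, 0, 0)).
Isotope-dilution concentrations convert p to natural Cd mass through the
¹¹⁰Cd atom fractions and mean atomic masses implied by the two
(fractionation-corrected) ratio sets.

The shipped reference and spike compositions
(`inst/extdata/cd_isotope_system.json`) are editable placeholders with a
natural-abundance-like reference and a notional ¹¹¹Cd–¹¹³Cd spike; tests use
self-consistent synthetic systems throughout and claim nothing about certified
values. Blank correction is not applied (procedural blanks in this kind of
workflow are negligible relative to sample Cd); the reduction operates on
blank-free ratios by design.

# Averaging and uncertainties

All isotope uncertainties are carried as 2sd, the convention in which
bracketing-standard reproducibility is reported. Inverse-variance weighting
(`ivw_mean()`) uses σ = 2sd/2, weights 1/σ², and reports the combined
uncertainty back on the 2sd scale. Within a treatment, apparent
fractionations (Δ) and per-plant ε estimates are computed per plant first and
then averaged across replicates — δ-type quantities by inverse variance,
masses, fractions and TF arithmetically. Δ values computed from
replicate-averaged δ values can differ from averaged per-plant Δ values by a
few hundredths of a permil; the per-plant-first order is the one consistent
with the replicate-averaging footnotes of the packaged tables, and the
packaged per-treatment tables are used as-printed in reproduction tests.

One documented discrepancy: the source study prints the initial-solution
composition once as +0.36‰ in running text and as −0.36 ± 0.04‰ in its table
footnote and figures. The package fixes δ_sol = −0.36‰ (`solution_delta()`),
treating the text value as a sign typo; all mass-balance arithmetic is
consistent with that choice.

# Group comparisons

`kruskal_wallis()` applies the tie-corrected Kruskal–Wallis test, the
appropriate omnibus choice for small, often non-normal samples. The p-value
comes from the χ² approximation (df = k − 1) above 12 total observations and
from exact enumeration of all assignments of the pooled values to the group
sizes at or below it. The cutoff of 12 keeps enumeration instantaneous at
desk scale (C(12,6) = 924 labelings) while covering the group sizes where the
χ² approximation is weakest; it is configurable. Pooled design-factor
comparisons (`pooled_group_compare()`) partition plants by a shared flag
(e.g. hydroponic Fe present/absent) exactly because per-treatment n is too
small for treatment-by-treatment testing.

# The synthetic generator

`simulate_experiment()` generates complete experiments with the statistical
structure the estimators assume:

- **Reservoir**: volume × concentration (defaults 3 L × 2.25 mg/L = 6750 µg
  Cd per treatment) at δ_init = −0.36‰.
- **Uptake**: each plant's uptake fraction is drawn i.i.d. uniform within
  ±20% of its treatment mean. The treatment means are the base uptake
  fraction (default 0.05 per three plants) scaled by an Fe multiplier
  (default 1.7) that is renormalised so the across-design mean stays at the
  base value. This interpretation keeps the design-mean plant Cd at
  6750·0.05/3 ≈ 112 µg and, with the ±20% spread, places hydroponic-Fe plants
  above 100 µg and TF > 100% and Fe-free plants below both — the grouping the
  generator is calibrated to emulate. Drawing uptake per plant (rather than
  splitting one treatment-level draw) keeps plants exchangeable under the
  null hypothesis, which is what makes the type-I-error calibration of the
  pooled tests meaningful.
- **Isotopes**: the total-plant δ comes from the accumulated-product Rayleigh
  relation at the treatment's remaining fraction; the leaf satisfies
  Δ_leaf-tot = ε_seq-mob·ln *f*_leaf exactly (default ε_seq-mob = −0.13‰);
  the stem sits at a configurable leaf-stem offset (default 0.23‰); the root
  closes the isotope mass balance. At zero noise every generated plant
  therefore satisfies the fitted model and all conservation identities to
  machine precision, and the fit recovers the generating ε exactly — asserted
  in tests.
- **Biomass**: total dry mass uniform on 0.57–0.99 g with a 63–78% leaf
  share, the observed ranges for seedlings of this kind; concentrations are
  back-computed so concentration × biomass reproduces organ Cd exactly.
- **Noise last**: Gaussian, independent across organs — δ noise with
  sd = 2sd/2 (default 2sd = 0.05‰, the typical analytical precision) and 5%
  relative concentration noise. Only reported values are perturbed; the truth
  table stays exact.

What the generator does *not* emulate: real biological covariance between
organs, adsorption losses, time-resolved uptake, speciation effects, foliar
absorption, or treatment-specific partitioning beyond the Fe shift. Passing
tests on synthetic data therefore demonstrate estimator correctness and
calibration under the stated statistical structure, not the biology of any
particular experiment.

# Numerical choices

- Newton inversion: relative residual tolerance 1e-12, max 100 iterations,
  step halving with a 1e-8 floor on the damping factor; non-convergence warns
  and is flagged, never silently accepted. p outside [0, 1] (beyond 1e-6) is
  flagged unphysical.
- Forced-origin fit: ε = Σ(w·x·y)/Σ(w·x²) with x = ln *f*; optional
  non-negative weights; a single point reduces exactly to the single-plant
  estimator; all *f* = 1 is a singular design error.
- Degenerate inputs: *f*_sink = 1 with Δ = 0 yields a flagged undefined ε
  (0/0), with Δ ≠ 0 it is an inconsistency error; zero root Cd makes TF an
  explicit error rather than Inf; `ivw_mean()` falls back to equal weights
  (flagged) when any uncertainty is missing or zero.
- Exact permutation p-values count H ≥ H_obs with a 1e-12 slack so ties in H
  at machine precision are included.
- All stored values are full precision; rounding to the two-decimal permil
  convention is left to display.

# Problem sizes

The test suite exercises the estimators at the scale of the emulated study:
16 analysed plants per experiment, 100-point inversion sweeps, 200-seed
recovery runs for the Rayleigh fit and a 1000-seed null calibration of the
pooled comparison. These sizes give Monte-Carlo standard errors comfortably
below the asserted bounds while keeping the default suite fast.

# Limitations

- The Rayleigh sink fit treats the accumulated sink with the instantaneous
  expression, as printed in the literature it mirrors; for large sink
  fractions the exact accumulated-product form diverges from it and should be
  preferred in new designs.
- Per-plant ε estimates degrade as *f*_sink → 1 (ln *f* → 0 amplifies Δ
  noise); the pooled fit weights such points down naturally through x² but
  single-plant values near *f* = 1 should be read with care.
- The double-spike module solves the standard three-ratio exponential-law
  system; it does not model interference corrections, cup-gain calibration or
  drift, which are assumed handled upstream.
- Uncertainty propagation is first-order (quadrature on fixed weights); no
  Monte-Carlo uncertainty on derived quantities is attempted.
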