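#' Define a Cd double-spike isotope system
#'
#' Holds the four isotope masses (110, 111, 113, 114) and the three ratios
#' (111/110, 113/110, 114/110) of the natural reference standard and of the
#' 111Cd-113Cd double spike, plus the spike solution's Cd content. The three
#' measured ratios of a spiked sample over-determine nothing: they are solved
#' exactly for the spike proportion and the natural and instrumental
#' exponential-law fractionation exponents.
#'
#' @param reference_ratios numeric length-3: standard 111/110, 113/110,
#'   114/110.
#' @param spike_ratios numeric length-3: same ratios for the double spike.
#' @param isotope_masses numeric length-4: atomic masses (u) of 110, 111, 113,
#'   114Cd; defaults to the atomic masses of those nuclides.
#' @param spike_conc_ng_g Cd amount per mass of spike solution (ng/g); optional,
#'   needed only for isotope-dilution concentrations from spike weights.
#' @return object of class `isotope_system`.
#' @seealso [default_isotope_system()] for the packaged placeholder
#'   compositions.
#' @export
isotope_system <- function(reference_ratios, spike_ratios,
                           isotope_masses = c(109.9030021, 110.9041781,
                                              112.9044017, 113.9033585),
                           spike_conc_ng_g = NA_real_) {
  stopifnot(length(reference_ratios) == 3, length(spike_ratios) == 3,
            length(isotope_masses) == 4)
  if (any(reference_ratios <= 0) || any(spike_ratios <= 0)) {
    stop("isotope_system: all ratios must be strictly positive")
  }
  if (any(diff(isotope_masses) <= 0)) {
    stop("isotope_system: isotope masses must be strictly increasing")
  }
  if (sum(abs(spike_ratios / reference_ratios - 1) > 1e-6) < 2) {
    stop("isotope_system: spike must differ from reference in at least two ratios (inversion singular)")
  }
  structure(list(
    isotope_masses = isotope_masses,
    reference_ratios = as.numeric(reference_ratios),
    spike_ratios = as.numeric(spike_ratios),
    spike_conc_ng_g = spike_conc_ng_g
  ), class = "isotope_system")
}

#' Packaged default isotope system
#'
#' Loads the isotope-system definition shipped at
#' `inst/extdata/cd_isotope_system.json`. The reference composition follows
#' representative natural Cd isotope abundances and the spike is a synthetic,
#' roughly equal-proportion 111Cd-113Cd mixture: these are editable
#' placeholder values for demonstration and testing, not certified
#' compositions of any real standard or spike batch.
#'
#' @param path optional path to an alternative JSON definition with fields
#'   `reference_ratios`, `spike_ratios`, `isotope_masses`, `spike_conc_ng_g`.
#' @return an [isotope_system()].
#' @export
default_isotope_system <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cd_isotope_system.json",
                        package = "cdisoflux", mustWork = TRUE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  isotope_system(cfg$reference_ratios, cfg$spike_ratios,
                 isotope_masses = cfg$isotope_masses,
                 spike_conc_ng_g = cfg$spike_conc_ng_g %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mass ratios m_i / m_110 for the three numerator isotopes (111, 113, 114)
.mass_ratios <- function(system) system$isotope_masses[2:4] / system$isotope_masses[1]

#' Forward model of a spiked, mass-biased ratio measurement
#'
#' Mixes an exponentially fractionated natural component with the spike on a
#' 110Cd-mole basis and applies instrumental mass bias, also with the
#' exponential law:
#' measured_i = (p * S_i + (1 - p) * R_i * g_i^alpha) * g_i^beta,
#' where g_i = m_i / m_110, R are the reference ratios and S the spike ratios.
#' alpha acts only on the natural component; beta on the mixture.
#'
#' @param p molar fraction of 110Cd-basis Cd deriving from the spike, in
#'   \[0, 1\].
#' @param alpha natural mass-dependent fractionation exponent (exponential
#'   law); the natural delta114Cd equals (g_114^alpha - 1) * 1000.
#' @param beta instrumental fractionation exponent.
#' @param system an [isotope_system()].
#' @return numeric length-3 vector of measured ratios (111/110, 113/110,
#'   114/110).
#' @export
forward_mix <- function(p, alpha, beta, system) {
  stopifnot(inherits(system, "isotope_system"))
  if (p < 0 || p > 1) stop("forward_mix: p must lie in [0, 1]")
  forward_mix_unchecked(p, alpha, beta, system)
}

# forward model without the [0, 1] guard: Newton iterates may step outside
forward_mix_unchecked <- function(p, alpha, beta, system) {
  g <- .mass_ratios(system)
  (p * system$spike_ratios + (1 - p) * system$reference_ratios * g^alpha) * g^beta
}

# analytic Jacobian of the forward model w.r.t. (p, alpha, beta)
.ds_jacobian <- function(p, alpha, beta, system) {
  g <- .mass_ratios(system)
  lg <- log(g)
  nat <- system$reference_ratios * g^alpha
  mix <- p * system$spike_ratios + (1 - p) * nat
  cbind((system$spike_ratios - nat) * g^beta,
        (1 - p) * nat * lg * g^beta,
        mix * lg * g^beta)
}

#' Natural delta114Cd implied by an exponential-law fractionation exponent
#'
#' @param alpha natural fractionation exponent.
#' @param system an [isotope_system()].
#' @return delta114Cd in permil relative to the system's reference.
#' @export
delta114_from_alpha <- function(alpha, system) {
  g114 <- system$isotope_masses[4] / system$isotope_masses[1]
  (g114^alpha - 1) * 1000
}

#' Invert a double-spike ratio measurement
#'
#' Solves the three-equation system forward_mix(p, alpha, beta) = measured for
#' the spike proportion p, the natural fractionation exponent alpha, and the
#' instrumental exponent beta, by damped Newton iteration with an analytic
#' Jacobian. A step is halved until it reduces the residual norm; convergence
#' requires a relative residual below `tol`.
#'
#' @param measured numeric length-3 measured ratios (111/110, 113/110,
#'   114/110).
#' @param system an [isotope_system()].
#' @param initial_guess numeric length-3 `(p, alpha, beta)` starting point.
#' @param tol relative residual tolerance.
#' @param max_iter maximum Newton iterations.
#' @return object of class `spike_mixture`: `p`, `alpha`, `beta`,
#'   `delta114_permil` (natural composition), `converged`, `iterations`,
#'   `residual` (relative norm), `physical` (p within \[0,1\] up to tol).
#' @export
invert_double_spike <- function(measured, system,
                                initial_guess = c(0.5, 0, 0),
                                tol = 1e-12, max_iter = 100L) {
  stopifnot(inherits(system, "isotope_system"), length(measured) == 3)
  if (any(measured <= 0)) stop("invert_double_spike: measured ratios must be positive")
  if (any(!is.finite(initial_guess))) stop("invert_double_spike: initial guess must be finite")
  scale <- sqrt(sum(measured^2))
  fn <- function(th) forward_mix_unchecked(th[1], th[2], th[3], system) - measured
  jac <- function(th) .ds_jacobian(th[1], th[2], th[3], system)

  th <- initial_guess
  r <- fn(th)
  rn <- sqrt(sum(r^2))
  iter <- 0L
  converged <- rn / scale < tol
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(jac(th), -r), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      th_new <- th + lambda * step
      r_new <- fn(th_new)
      rn_new <- sqrt(sum(r_new^2))
      if (rn_new < rn || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (rn_new >= rn && lambda < 1e-8) break  # stagnated
    th <- th_new; r <- r_new; rn <- rn_new
    if (rn / scale < tol) { converged <- TRUE; break }
  }

  p <- th[1]
  physical <- p >= -1e-6 && p <= 1 + 1e-6
  out <- structure(list(
    p = p, alpha = th[2], beta = th[3],
    delta114_permil = delta114_from_alpha(th[2], system),
    converged = converged, iterations = iter,
    residual = rn / scale, physical = physical,
    measured_ratios = measured
  ), class = "spike_mixture")
  if (!converged) {
    warning(sprintf(
      "double-spike inversion did not converge after %d iterations (relative residual %.3e)",
      iter, rn / scale))
  }
  out
}

#' @export
print.spike_mixture <- function(x, ...) {
  cat(sprintf(
    "double-spike inversion: p = %.6f, alpha = %.3e, beta = %.4f\n  natural delta114Cd = %.4f permil; %s in %d iterations (residual %.2e)%s\n",
    x$p, x$alpha, x$beta, x$delta114_permil,
    if (x$converged) "converged" else "NOT converged", x$iterations, x$residual,
    if (x$physical) "" else " [p unphysical]"))
  invisible(x)
}

# 110Cd atom fraction and mean atomic mass implied by a set of ratios
.composition_from_ratios <- function(ratios, masses) {
  ab110 <- 1 / (1 + sum(ratios))
  ab <- ab110 * c(1, ratios)
  list(a110 = ab110, atomic_mass = sum(ab * masses))
}

#' Isotope-dilution Cd quantification
#'
#' Converts an inverted spike proportion into a natural Cd concentration. On a
#' 110Cd-mole basis, n110_natural / n110_spike = (1 - p) / p; the 110Cd moles
#' are converted to total Cd masses through the 110Cd atom fractions and mean
#' atomic masses implied by the (fractionation-corrected) natural and spike
#' ratio sets.
#'
#' @param mix a `spike_mixture` from [invert_double_spike()], or a bare value
#'   of p.
#' @param spike_cd_ng total spike-derived Cd added, in ng. Alternatively
#'   supply `spike_mass_g` with a system whose `spike_conc_ng_g` is set.
#' @param sample_dry_mass_g digested sample dry mass in g.
#' @param system an [isotope_system()].
#' @param spike_mass_g mass of spike solution added (g), used with
#'   `system$spike_conc_ng_g` when `spike_cd_ng` is missing.
#' @return list with `conc_mg_per_kg`, `natural_cd_ng`, `spike_cd_ng`, `p`.
#' @export
isotope_dilution_conc <- function(mix, spike_cd_ng = NULL, sample_dry_mass_g,
                                  system, spike_mass_g = NULL) {
  p <- if (inherits(mix, "spike_mixture")) {
    if (!mix$converged) stop("isotope_dilution_conc: inversion did not converge")
    mix$p
  } else mix
  alpha <- if (inherits(mix, "spike_mixture")) mix$alpha else 0
  if (is.null(spike_cd_ng)) {
    if (is.null(spike_mass_g) || is.na(system$spike_conc_ng_g)) {
      stop("isotope_dilution_conc: supply spike_cd_ng, or spike_mass_g with a system spike_conc_ng_g")
    }
    spike_cd_ng <- spike_mass_g * system$spike_conc_ng_g
  }
  stopifnot(sample_dry_mass_g > 0, spike_cd_ng >= 0)
  if (p <= 0) stop("isotope_dilution_conc: p = 0, no spike detected")
  if (p >= 1) {
    warning("isotope_dilution_conc: p = 1, no natural Cd detected")
    return(list(conc_mg_per_kg = 0, natural_cd_ng = 0,
                spike_cd_ng = spike_cd_ng, p = p))
  }
  g <- .mass_ratios(system)
  nat <- .composition_from_ratios(system$reference_ratios * g^alpha,
                                  system$isotope_masses)
  spk <- .composition_from_ratios(system$spike_ratios, system$isotope_masses)
  n110_spike <- spike_cd_ng / spk$atomic_mass * spk$a110   # n-mol of 110Cd
  n110_nat <- n110_spike * (1 - p) / p
  natural_cd_ng <- n110_nat / nat$a110 * nat$atomic_mass
  # ng / g = ug/kg; mg/kg = ng/g / 1000
  list(conc_mg_per_kg = natural_cd_ng / sample_dry_mass_g / 1000,
       natural_cd_ng = natural_cd_ng, spike_cd_ng = spike_cd_ng, p = p)
}

#' Plan the spike addition for a sample
#'
#' Chooses a spike Cd mass such that the spike-derived to natural Cd mass
#' ratio falls in a target range and the total Cd in the processed aliquot
#' falls in a target window (typical practice: spike:natural between 1 and 2
#' with 200-300 ng total Cd). Returns the midpoint of the feasible interval,
#' or an explicit infeasibility flag; the joint constraint is never silently
#' clamped.
#'
#' @param estimated_natural_cd_ng preliminary estimate of natural Cd in the
#'   aliquot (ng), > 0.
#' @param target_ratio_range length-2: (low, high) spike:natural mass ratio.
#' @param target_total_ng length-2: (low, high) total Cd window (ng).
#' @return list with `feasible`, `spike_cd_ng` (midpoint, NA if infeasible),
#'   `spike_range_ng` (feasible interval), `expected_total_ng`.
#' @export
plan_spike <- function(estimated_natural_cd_ng,
                       target_ratio_range = c(1, 2),
                       target_total_ng = c(200, 300)) {
  if (estimated_natural_cd_ng <= 0) stop("plan_spike: natural Cd estimate must be > 0")
  stopifnot(target_ratio_range[1] < target_ratio_range[2],
            target_total_ng[1] < target_total_ng[2])
  nat <- estimated_natural_cd_ng
  lo <- max(target_ratio_range[1] * nat, target_total_ng[1] - nat)
  hi <- min(target_ratio_range[2] * nat, target_total_ng[2] - nat)
  if (lo > hi || hi <= 0) {
    return(list(feasible = FALSE, spike_cd_ng = NA_real_,
                spike_range_ng = c(NA_real_, NA_real_),
                expected_total_ng = NA_real_))
  }
  lo <- max(lo, 0)
  mid <- (lo + hi) / 2
  list(feasible = TRUE, spike_cd_ng = mid, spike_range_ng = c(lo, hi),
       expected_total_ng = nat + mid)
}

#' Reduce a table of spiked ratio measurements
#'
#' Batch double-spike reduction: inverts each measured ratio triple and, when
#' spike and sample masses are available, computes isotope-dilution Cd
#' concentrations.
#'
#' @param ratios a data frame (or CSV path) with columns `sample_id`,
#'   `r111_110`, `r113_110`, `r114_110` and optionally `spike_mass_g`,
#'   `sample_dry_mass_g`.
#' @param system an [isotope_system()].
#' @param tol,max_iter passed to [invert_double_spike()].
#' @return tibble with `sample_id`, `p`, `alpha`, `beta`, `delta114_permil`,
#'   `conc_mg_per_kg`, `converged`, `iterations`, `residual`.
#' @export
reduce_spiked_ratios <- function(ratios, system, tol = 1e-12, max_iter = 100L) {
  if (is.character(ratios)) {
    ratios <- utils::read.csv(ratios, stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "r111_110", "r113_110", "r114_110")
  if (!all(need %in% names(ratios))) {
    stop("reduce_spiked_ratios: need columns ", paste(need, collapse = ", "))
  }
  has_id <- all(c("spike_mass_g", "sample_dry_mass_g") %in% names(ratios))
  rows <- lapply(seq_len(nrow(ratios)), function(i) {
    m <- as.numeric(ratios[i, c("r111_110", "r113_110", "r114_110")])
    inv <- invert_double_spike(m, system, tol = tol, max_iter = max_iter)
    conc <- NA_real_
    if (has_id && inv$converged && inv$p > 0 && inv$p < 1) {
      conc <- isotope_dilution_conc(
        inv, sample_dry_mass_g = ratios$sample_dry_mass_g[i],
        system = system, spike_mass_g = ratios$spike_mass_g[i])$conc_mg_per_kg
    }
    tibble::tibble(sample_id = ratios$sample_id[i], p = inv$p,
                   alpha = inv$alpha, beta = inv$beta,
                   delta114_permil = inv$delta114_permil,
                   conc_mg_per_kg = conc, converged = inv$converged,
                   iterations = inv$iterations, residual = inv$residual)
  })
  dplyr::bind_rows(rows)
}
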