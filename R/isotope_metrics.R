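#' Delta value with analytical uncertainty
#'
#' Bundles a delta114Cd value (permil vs. the NIST SRM-3108 standard) with its
#' analytical 2sd and the number of replicate measurements it represents.
#' Uncertainties are stored throughout as 2sd, the convention used for
#' MC-ICP-MS bracketing-standard reproducibility.
#'
#' @param value delta114Cd in permil.
#' @param two_sd analytical 2sd in permil (non-negative).
#' @param n number of replicate measurements (>= 1).
#' @return A `delta_value` object (named list).
#' @export
#' @examples
#' delta_value(-0.36, two_sd = 0.04, n = 6)
delta_value <- function(value, two_sd = NA_real_, n = 1L) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (!is.na(two_sd) && two_sd < 0) stop("two_sd must be >= 0")
  if (n < 1) stop("n must be >= 1")
  structure(list(value = value, two_sd = as.numeric(two_sd), n = as.integer(n)),
            class = "delta_value")
}

#' @export
print.delta_value <- function(x, ...) {
  cat(sprintf("delta114Cd = %.3f +/- %.3f permil (2sd, n = %d)\n",
              x$value, x$two_sd, x$n))
  invisible(x)
}

#' Convert an isotope ratio to delta notation
#'
#' delta = (R_sample / R_standard - 1) * 1000, in permil. The denominator
#' ratio is 114Cd/110Cd of the reference standard.
#'
#' @param r_sample sample 114Cd/110Cd ratio (> 0).
#' @param r_standard standard 114Cd/110Cd ratio (> 0).
#' @return delta value in permil.
#' @seealso [ratio_from_delta()] for the exact inverse.
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0)) {
    stop("isotope ratios must be strictly positive")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Convert a delta value back to an isotope ratio
#'
#' @param delta delta value in permil.
#' @param r_standard standard ratio (> 0).
#' @return sample ratio.
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(r_standard <= 0)) stop("isotope ratios must be strictly positive")
  r_standard * (1 + delta / 1000)
}

#' Apparent isotope fractionation between two pools
#'
#' Delta114Cd_A-B = delta_A - delta_B. When `delta_value` objects are supplied
#' the 2sd uncertainties are propagated in quadrature.
#'
#' @param delta_a,delta_b delta values in permil, either bare numerics or
#'   [delta_value()] objects.
#' @return numeric permil difference, or a `delta_value` when both inputs carry
#'   uncertainties.
#' @export
#' @examples
#' capital_delta(-0.67, -0.36)  # total plant vs. solution: -0.31
capital_delta <- function(delta_a, delta_b) {
  if (inherits(delta_a, "delta_value") || inherits(delta_b, "delta_value")) {
    a <- if (inherits(delta_a, "delta_value")) delta_a else delta_value(delta_a)
    b <- if (inherits(delta_b, "delta_value")) delta_b else delta_value(delta_b)
    sd2 <- sqrt(sum(c(a$two_sd, b$two_sd)^2, na.rm = TRUE))
    return(delta_value(a$value - b$value, two_sd = sd2))
  }
  delta_a - delta_b
}

#' Inverse-variance weighted mean of delta values
#'
#' Weights are w_i = 1/sigma_i^2 with sigma_i = two_sd_i / 2; the combined
#' uncertainty is reported back on the 2sd scale as 2 / sqrt(sum(w)). If any
#' uncertainty is missing or zero the mean falls back to equal weights and the
#' result is flagged via the `equal_weights` attribute.
#'
#' @param values list of [delta_value()] objects, or a numeric vector (equal
#'   weights).
#' @return A `delta_value` with the weighted mean and combined 2sd.
#' @export
#' @examples
#' ivw_mean(list(delta_value(0.0, 0.1), delta_value(0.5, 0.2)))  # mean 0.1
ivw_mean <- function(values) {
  if (is.numeric(values)) values <- lapply(values, delta_value)
  if (length(values) == 0) stop("ivw_mean: empty input")
  x <- vapply(values, function(v) v$value, numeric(1))
  s2 <- vapply(values, function(v) v$two_sd, numeric(1)) / 2
  equal <- any(is.na(s2)) || any(s2 == 0)
  if (equal) {
    out <- delta_value(mean(x), two_sd = if (length(x) > 1) 2 * stats::sd(x) / sqrt(length(x)) else NA_real_,
                       n = length(x))
  } else {
    w <- 1 / s2^2
    out <- delta_value(sum(w * x) / sum(w), two_sd = 2 / sqrt(sum(w)), n = length(x))
  }
  attr(out, "equal_weights") <- equal
  out
}

#' Molar and mass concentration conversions
#'
#' Convenience conversions between micromolar and mg/L (or ug/L) element
#' concentrations, used when translating hydroponic recipes (e.g. 20 umol/L
#' CdCl2 equals 2.25 mg/L Cd).
#'
#' @param umol_per_l concentration in umol/L.
#' @param mg_per_l concentration in mg/L.
#' @param molar_mass_g_mol molar mass of the element in g/mol; the packaged
#'   [element_molar_mass()] helper supplies Cd, Zn and Fe.
#' @return the converted concentration.
#' @export
umol_to_mg_per_l <- function(umol_per_l, molar_mass_g_mol) {
  umol_per_l * molar_mass_g_mol / 1000
}

#' @rdname umol_to_mg_per_l
#' @export
mg_to_umol_per_l <- function(mg_per_l, molar_mass_g_mol) {
  mg_per_l / molar_mass_g_mol * 1000
}

#' @rdname umol_to_mg_per_l
#' @param element element symbol: "Cd", "Zn" or "Fe".
#' @export
element_molar_mass <- function(element) {
  masses <- c(Cd = 112.414, Zn = 65.38, Fe = 55.845)
  if (!element %in% names(masses)) stop("unknown element: ", element)
  unname(masses[element])
}

#' Cd mass held in one organ
#'
#' Concentration (mg/kg dry weight) times dry biomass (g) gives micrograms of
#' Cd, since mg/kg equals ug/g.
#'
#' @param conc_mg_per_kg Cd concentration in mg/kg dry weight.
#' @param dry_mass_g organ dry biomass in g.
#' @return Cd mass in ug.
#' @export
organ_cd_mass <- function(conc_mg_per_kg, dry_mass_g) {
  conc_mg_per_kg * dry_mass_g
}

#' Per-plant Cd mass balance
#'
#' Derives, for one plant, the organ Cd masses, the total plant Cd, the
#' Cd-mass-weighted total-plant delta114Cd, the partition fractions of total
#' Cd per organ (f_leaf, f_stem, f_root, f_shoot = f_leaf + f_stem) and the
#' root-to-shoot translocation factor.
#'
#' @param organs a data frame with one row per organ and columns `organ`
#'   (character: "root", "stem", "leaf"), `dry_mass_g`, `conc_mg_per_kg`,
#'   `delta114_permil` and optionally `two_sd_permil`.
#' @return A one-row [tibble::tibble()] with columns `cd_root_ug`,
#'   `cd_stem_ug`, `cd_leaf_ug`, `total_cd_ug`, `delta_tot`, `delta_tot_2sd`,
#'   `f_root`, `f_stem`, `f_leaf`, `f_shoot`, `tf_percent`, `complete`
#'   (logical: all three organs present).
#' @export
plant_totals <- function(organs) {
  stopifnot(is.data.frame(organs), nrow(organs) >= 1)
  need <- c("organ", "dry_mass_g", "conc_mg_per_kg", "delta114_permil")
  missing_cols <- setdiff(need, names(organs))
  if (length(missing_cols)) stop("plant_totals: missing columns: ",
                                 paste(missing_cols, collapse = ", "))
  if (anyDuplicated(organs$organ)) stop("plant_totals: duplicated organ labels")
  if (!all(organs$organ %in% c("root", "stem", "leaf"))) {
    stop("plant_totals: organ must be one of root/stem/leaf")
  }
  if (any(organs$dry_mass_g <= 0)) stop("plant_totals: dry_mass_g must be > 0")
  if (any(organs$conc_mg_per_kg < 0)) stop("plant_totals: conc must be >= 0")

  cd <- stats::setNames(rep(NA_real_, 3), c("root", "stem", "leaf"))
  dl <- sd2 <- cd
  for (i in seq_len(nrow(organs))) {
    o <- organs$organ[i]
    cd[o] <- organ_cd_mass(organs$conc_mg_per_kg[i], organs$dry_mass_g[i])
    dl[o] <- organs$delta114_permil[i]
    sd2[o] <- if ("two_sd_permil" %in% names(organs)) organs$two_sd_permil[i] else NA_real_
  }
  present <- !is.na(cd)
  total <- sum(cd[present])
  f <- cd / total
  # mass-weighted total delta; 2sd propagated through the fixed weights
  w <- cd[present] / total
  delta_tot <- sum(w * dl[present])
  delta_tot_2sd <- if (all(!is.na(sd2[present]))) sqrt(sum((w * sd2[present])^2)) else NA_real_
  f_shoot <- sum(f[c("stem", "leaf")], na.rm = all(present[c("stem", "leaf")]))
  tf <- if (present["root"] && cd["root"] > 0) {
    sum(cd[c("leaf", "stem")], na.rm = TRUE) / cd[["root"]] * 100
  } else NA_real_

  tibble::tibble(
    cd_root_ug = cd[["root"]], cd_stem_ug = cd[["stem"]], cd_leaf_ug = cd[["leaf"]],
    total_cd_ug = total,
    delta_tot = delta_tot, delta_tot_2sd = delta_tot_2sd,
    f_root = f[["root"]], f_stem = f[["stem"]], f_leaf = f[["leaf"]],
    f_shoot = if (all(present[c("stem", "leaf")])) f[["stem"]] + f[["leaf"]] else NA_real_,
    tf_percent = tf,
    complete = all(present)
  )
}

#' Root-to-shoot translocation factor
#'
#' TF(%) = (Cd_leaf + Cd_stem) / Cd_root * 100. TF = 100% is the natural
#' boundary between root-dominated and shoot-dominated Cd inventories.
#'
#' @param cd_leaf_ug,cd_stem_ug,cd_root_ug organ Cd masses in ug.
#' @return TF in percent.
#' @export
translocation_factor <- function(cd_leaf_ug, cd_stem_ug, cd_root_ug) {
  if (any(cd_root_ug <= 0)) stop("translocation factor undefined: root Cd mass must be > 0")
  (cd_leaf_ug + cd_stem_ug) / cd_root_ug * 100
}

#' Derive per-plant quantities from a long measurement table
#'
#' Applies [plant_totals()] to every (treatment, replicate) group of a long
#' per-organ table, carrying the design flags through, and appends the
#' within-plant apparent fractionations (leaf-stem, stem-root, leaf-root,
#' leaf-total, shoot-total) plus per-plant Rayleigh fractionation-factor
#' estimates for leaf and shoot sinks.
#'
#' @param plants long table in the `plants.csv` schema: `treatment_id`,
#'   `replicate_id`, `hydro_fe`, `hydro_zn`, `foliar_fe`, `foliar_zn`,
#'   `organ`, `dry_mass_g`, `conc_mg_per_kg`, `delta114_permil`,
#'   `two_sd_permil`.
#' @param delta_sol delta114Cd of the Cd source solution (permil); default
#'   -0.36.
#' @return tibble with one row per plant.
#' @export
derive_plants <- function(plants, delta_sol = -0.36) {
  stopifnot(is.data.frame(plants), nrow(plants) >= 1)
  sol <- if (inherits(delta_sol, "delta_value")) delta_sol$value else delta_sol
  key <- paste(plants$treatment_id, plants$replicate_id, sep = "\r")
  if (anyDuplicated(paste(key, plants$organ))) {
    stop("derive_plants: duplicated (treatment, replicate, organ)")
  }
  if (!all(plants$organ %in% c("root", "stem", "leaf"))) {
    stop("derive_plants: organ must be one of root/stem/leaf")
  }
  if (any(plants$dry_mass_g <= 0)) stop("derive_plants: dry_mass_g must be > 0")
  if (any(plants$conc_mg_per_kg < 0)) stop("derive_plants: conc must be >= 0")
  ukey <- unique(key)
  # per-organ columns aligned to the unique plant keys
  pull <- function(col, o) {
    sel <- plants$organ == o
    if (!col %in% names(plants)) return(rep(NA_real_, length(ukey)))
    plants[[col]][sel][match(ukey, key[sel])]
  }
  cd <- lapply(c(root = "root", stem = "stem", leaf = "leaf"), function(o) {
    organ_cd_mass(pull("conc_mg_per_kg", o), pull("dry_mass_g", o))
  })
  dl <- lapply(c(root = "root", stem = "stem", leaf = "leaf"),
               function(o) pull("delta114_permil", o))
  s2 <- lapply(c(root = "root", stem = "stem", leaf = "leaf"),
               function(o) pull("two_sd_permil", o))
  cdm <- cbind(cd$root, cd$stem, cd$leaf)
  total <- rowSums(cdm, na.rm = TRUE)
  f_root <- cd$root / total; f_stem <- cd$stem / total; f_leaf <- cd$leaf / total
  # mass-weighted total delta; 2sd propagated through the fixed weights
  wsum <- function(fun) {
    m <- cbind(fun(f_root, dl$root, s2$root), fun(f_stem, dl$stem, s2$stem),
               fun(f_leaf, dl$leaf, s2$leaf))
    rowSums(m, na.rm = TRUE)
  }
  delta_tot <- wsum(function(w, d, s) w * d)
  delta_tot_2sd <- sqrt(wsum(function(w, d, s) (w * s)^2))
  complete <- !is.na(cd$root) & !is.na(cd$stem) & !is.na(cd$leaf)
  sd_missing <- (!is.na(f_root) & is.na(s2$root)) |
    (!is.na(f_stem) & is.na(s2$stem)) | (!is.na(f_leaf) & is.na(s2$leaf))
  delta_tot_2sd[sd_missing] <- NA_real_
  f_shoot <- f_stem + f_leaf
  shoot_cd <- cd$stem + cd$leaf
  delta_shoot <- (cd$leaf * dl$leaf + cd$stem * dl$stem) / shoot_cd
  tf <- ifelse(!is.na(cd$root) & cd$root > 0,
               (ifelse(is.na(cd$leaf), 0, cd$leaf) +
                  ifelse(is.na(cd$stem), 0, cd$stem)) / cd$root * 100, NA_real_)
  d_l_tot <- dl$leaf - delta_tot
  d_sh_tot <- delta_shoot - delta_tot
  eps_ok <- function(f) !is.na(f) & f > 0 & f < 1
  eps_leaf <- ifelse(eps_ok(f_leaf), d_l_tot / log(f_leaf), NA_real_)
  eps_shoot <- ifelse(eps_ok(f_shoot), d_sh_tot / log(f_shoot), NA_real_)

  first <- match(ukey, key)
  design_cols <- intersect(c("hydro_fe", "hydro_zn", "foliar_fe", "foliar_zn"),
                           names(plants))
  out <- tibble::tibble(
    treatment_id = plants$treatment_id[first],
    replicate_id = plants$replicate_id[first]
  )
  for (cl in design_cols) out[[cl]] <- plants[[cl]][first]
  tibble::as_tibble(cbind(out, tibble::tibble(
    cd_root_ug = cd$root, cd_stem_ug = cd$stem, cd_leaf_ug = cd$leaf,
    total_cd_ug = total,
    delta_tot = delta_tot, delta_tot_2sd = delta_tot_2sd,
    f_root = f_root, f_stem = f_stem, f_leaf = f_leaf,
    f_shoot = f_shoot, tf_percent = tf, complete = complete,
    conc_root = pull("conc_mg_per_kg", "root"),
    conc_stem = pull("conc_mg_per_kg", "stem"),
    conc_leaf = pull("conc_mg_per_kg", "leaf"),
    delta_root = dl$root, delta_stem = dl$stem, delta_leaf = dl$leaf,
    delta_shoot = delta_shoot,
    two_sd_root = s2$root, two_sd_stem = s2$stem, two_sd_leaf = s2$leaf,
    d_ls = dl$leaf - dl$stem, d_sr = dl$stem - dl$root,
    d_lr = dl$leaf - dl$root,
    d_tot_sol = delta_tot - sol,
    d_l_tot = d_l_tot, d_sh_tot = d_sh_tot,
    eps_seq_mob_leaf = eps_leaf, eps_seq_mob_shoot = eps_shoot
  )))
}

#' Per-treatment summary of derived plant quantities
#'
#' Computes the per-plant apparent fractionations and fractionation-factor
#' estimates first, then averages across the replicates of each treatment:
#' inverse-variance weighting for delta-derived quantities (organ deltas and
#' the total-plant delta, using each plant's propagated 2sd) and arithmetic
#' means for masses, concentrations, partition fractions and translocation
#' factors. Delta differences and Rayleigh estimates are averaged
#' arithmetically across replicates because their per-plant uncertainties are
#' strongly correlated through the shared total-plant delta.
#'
#' @inheritParams derive_plants
#' @return tibble with one row per treatment: weighted organ/total deltas,
#'   mean concentrations and Cd masses, the Delta set (`d_ls`, `d_sr`, `d_lr`,
#'   `d_tot_sol`, `d_l_tot`, `d_sh_tot`), `eps_seq_mob_leaf`/`_shoot`, mean TF
#'   and partition fractions, and `n_plants`.
#' @seealso [grand_means()] for the across-treatment mean row.
#' @export
treatment_summary <- function(plants, delta_sol = -0.36) {
  per_plant <- derive_plants(plants, delta_sol = delta_sol)
  if (nrow(per_plant) == 0) stop("treatment_summary: no plants")
  ivw_col <- function(sub, vcol, scol) {
    ok <- !is.na(sub[[vcol]])
    if (!any(ok)) return(NA_real_)
    ivw_mean(Map(delta_value, sub[[vcol]][ok], sub[[scol]][ok]))$value
  }
  split_idx <- split(seq_len(nrow(per_plant)), per_plant$treatment_id)
  rows <- lapply(split_idx, function(idx) {
    sub <- per_plant[idx, , drop = FALSE]
    design <- sub[1, intersect(c("hydro_fe", "hydro_zn", "foliar_fe", "foliar_zn"),
                               names(sub)), drop = FALSE]
    m <- function(x) mean(x, na.rm = TRUE)
    tibble::as_tibble(cbind(
      data.frame(treatment_id = sub$treatment_id[1], n_plants = nrow(sub)),
      design,
      data.frame(
        total_cd_ug = m(sub$total_cd_ug),
        conc_root = m(sub$conc_root), conc_stem = m(sub$conc_stem),
        conc_leaf = m(sub$conc_leaf),
        cd_root_ug = m(sub$cd_root_ug), cd_stem_ug = m(sub$cd_stem_ug),
        cd_leaf_ug = m(sub$cd_leaf_ug),
        delta_root = ivw_col(sub, "delta_root", "two_sd_root"),
        delta_stem = ivw_col(sub, "delta_stem", "two_sd_stem"),
        delta_leaf = ivw_col(sub, "delta_leaf", "two_sd_leaf"),
        delta_tot = ivw_col(sub, "delta_tot", "delta_tot_2sd"),
        d_ls = m(sub$d_ls), d_sr = m(sub$d_sr), d_lr = m(sub$d_lr),
        d_tot_sol = m(sub$d_tot_sol), d_l_tot = m(sub$d_l_tot),
        d_sh_tot = m(sub$d_sh_tot),
        eps_seq_mob_leaf = m(sub$eps_seq_mob_leaf),
        eps_seq_mob_shoot = m(sub$eps_seq_mob_shoot),
        tf_percent = m(sub$tf_percent),
        f_root = m(sub$f_root), f_stem = m(sub$f_stem), f_leaf = m(sub$f_leaf),
        f_shoot = m(sub$f_shoot),
        replicates = paste(sub$replicate_id, collapse = ",")
      )
    ))
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$treatment_id), , drop = FALSE]
}

#' Across-treatment grand means
#'
#' Arithmetic mean and sd of each numeric column across the treatment rows of
#' a summary table — the analogue of a printed "Mean"/"sd" row computed from
#' per-treatment values (n = number of treatments), not from individual
#' replicates.
#'
#' @param summary_tbl a tibble of per-treatment values (e.g. from
#'   [treatment_summary()] or a packaged printed table).
#' @param cols columns to average; default all numeric columns except
#'   `n_plants`.
#' @return tibble with rows `mean` and `sd`.
#' @export
grand_means <- function(summary_tbl, cols = NULL) {
  num <- vapply(summary_tbl, is.numeric, logical(1))
  if (is.null(cols)) cols <- setdiff(names(summary_tbl)[num], "n_plants")
  mu <- vapply(cols, function(cl) mean(summary_tbl[[cl]], na.rm = TRUE), numeric(1))
  sg <- vapply(cols, function(cl) stats::sd(summary_tbl[[cl]], na.rm = TRUE), numeric(1))
  out <- tibble::as_tibble(rbind(mu, sg))
  out$statistic <- c("mean", "sd")
  out[, c("statistic", cols)]
}

#' Final-solution isotope bookkeeping
#'
#' Exact two-pool mass balance for a closed hydroponic reservoir: the plants
#' remove a Cd mass with weighted composition delta_plants, leaving a fraction
#' f of the initial Cd with composition delta_final such that
#' f * delta_final + (1 - f) * delta_plants = delta_init.
#'
#' @param delta_init initial solution delta114Cd (permil), numeric or
#'   [delta_value()].
#' @param cd_mass_init_ug initial reservoir Cd mass (ug).
#' @param plant_cd_ug vector of plant total Cd masses (ug).
#' @param plant_delta vector of plant total delta114Cd (permil).
#' @return list with `f_remaining`, `delta_final`, `delta_plants_weighted`,
#'   `cd_removed_ug`.
#' @export
#' @examples
#' final_solution_state(-0.36, 6750, plant_cd_ug = 337.5, plant_delta = -0.635)
final_solution_state <- function(delta_init, cd_mass_init_ug, plant_cd_ug,
                                 plant_delta) {
  d0 <- if (inherits(delta_init, "delta_value")) delta_init$value else delta_init
  stopifnot(cd_mass_init_ug > 0, length(plant_cd_ug) == length(plant_delta))
  removed <- sum(plant_cd_ug)
  if (removed >= cd_mass_init_ug) {
    stop("mass-balance violation: plants contain more Cd than the reservoir held")
  }
  f <- 1 - removed / cd_mass_init_ug
  if (removed == 0) {
    return(list(f_remaining = 1, delta_final = d0,
                delta_plants_weighted = NA_real_, cd_removed_ug = 0))
  }
  d_plants <- sum(plant_cd_ug * plant_delta) / removed
  d_final <- (d0 - (1 - f) * d_plants) / f
  list(f_remaining = f, delta_final = d_final,
       delta_plants_weighted = d_plants, cd_removed_ug = removed)
}

#' Reconstruct the final-solution composition from an apparent fractionation
#'
#' Given the apparent total-plant-minus-solution fractionation of a treatment
#' and the uptake fraction, rebuilds the final-solution delta114Cd by exact
#' two-pool mass balance (the plant pool sits at delta_init + d_tot_sol).
#'
#' @param d_tot_sol apparent fractionation Delta114Cd_tot-sol (permil).
#' @param delta_init initial solution delta114Cd (permil).
#' @param f_remaining fraction of reservoir Cd left (0 < f < 1).
#' @return final-solution delta114Cd (permil).
#' @export
reconstruct_final_solution <- function(d_tot_sol, delta_init = -0.36,
                                       f_remaining = 0.95) {
  stopifnot(f_remaining > 0, f_remaining < 1)
  vapply(d_tot_sol, function(d) {
    final_solution_state(delta_init, 1,
                         plant_cd_ug = 1 - f_remaining,
                         plant_delta = delta_init + d)$delta_final
  }, numeric(1))
}
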