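#' Configuration for a synthetic hydroponic Cd experiment
#'
#' Describes a closed-system hydroponic design: a finite Cd reservoir per
#' treatment, plants that remove a few percent of it in one Rayleigh step,
#' within-plant partitioning that follows the sequestration/mobilisation
#' relation exactly before noise, a phenomenological Fe effect (multiplier on
#' uptake, shift in the leaf fraction), and Gaussian analytical noise applied
#' last. Defaults emulate the eight-treatment cacao study design: 3 L of
#' 2.25 mg/L Cd (20 umol/L CdCl2) per treatment, source delta114Cd -0.36
#' permil, mean uptake of 5% of the reservoir per three plants, uptake
#' fractionation -0.29 permil, sequestration/mobilisation fractionation -0.13
#' permil, total dry biomass 0.57-0.99 g with 63-78% in leaves, and analytical
#' precision of 0.05 permil (2sd) on delta and 5% relative on concentrations.
#'
#' @param seed integer seed for reproducibility, or `NULL` to leave the RNG
#'   state alone.
#' @param treatments data frame of design flags `treatment_id`, `hydro_fe`,
#'   `hydro_zn`, `foliar_fe`, `foliar_zn`; defaults to the eight-treatment
#'   design of [cacao_table1()].
#' @param replicates_grown plants grown per treatment (default 3).
#' @param replicates_analysed plants selected for isotope analysis (default 2).
#' @param solution_volume_l,solution_conc_mg_l reservoir volume (L) and Cd
#'   concentration (mg/L).
#' @param delta_init source solution delta114Cd (permil).
#' @param epsilon_uptake,epsilon_seq_mob fractionation factors (permil).
#' @param base_uptake_fraction design-mean fraction of reservoir Cd removed by
#'   the plants of one treatment; the Fe multiplier is renormalised around this
#'   mean so the across-treatment average uptake stays at the base value.
#' @param fe_uptake_multiplier uptake multiplier for hydroponic-Fe treatments
#'   relative to Fe-free ones.
#' @param uptake_jitter half-width of the relative uniform jitter on each
#'   plant's uptake fraction (default 0.2, spreading treatment uptake over
#'   roughly 3-8% while keeping hydroponic-Fe plants above 100 ug total Cd and
#'   Fe-free plants below).
#' @param f_leaf_base mean fraction of plant Cd in leaves for hydroponic-Fe
#'   treatments.
#' @param fe_fshoot_shift reduction of the leaf Cd fraction when hydroponic Fe
#'   is absent (enhanced root sequestration).
#' @param f_leaf_jitter,f_stem_base,f_stem_jitter uniform spread of the leaf
#'   fraction; mean and spread of the stem fraction.
#' @param d_ls_target leaf-stem apparent fractionation (permil) the generator
#'   centres the stem composition on.
#' @param biomass_range_g,leaf_share_range uniform ranges for total dry
#'   biomass and the leaf share of it.
#' @param noise_delta_2sd analytical 2sd on delta values (permil).
#' @param noise_conc_rel relative 1sd noise on concentrations.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = NULL,
                       treatments = NULL,
                       replicates_grown = 3L,
                       replicates_analysed = 2L,
                       solution_volume_l = 3,
                       solution_conc_mg_l = 2.25,
                       delta_init = -0.36,
                       epsilon_uptake = -0.29,
                       epsilon_seq_mob = -0.13,
                       base_uptake_fraction = 0.05,
                       fe_uptake_multiplier = 1.7,
                       uptake_jitter = 0.2,
                       f_leaf_base = 0.47,
                       fe_fshoot_shift = 0.17,
                       f_leaf_jitter = 0.05,
                       f_stem_base = 0.12,
                       f_stem_jitter = 0.02,
                       d_ls_target = 0.23,
                       biomass_range_g = c(0.57, 0.99),
                       leaf_share_range = c(0.63, 0.78),
                       noise_delta_2sd = 0.05,
                       noise_conc_rel = 0.05) {
  if (is.null(treatments)) {
    treatments <- cacao_table1()[, c("treatment_id", "hydro_fe", "hydro_zn",
                                     "foliar_fe", "foliar_zn")]
  }
  cfg <- list(seed = seed, treatments = treatments,
              replicates_grown = as.integer(replicates_grown),
              replicates_analysed = as.integer(replicates_analysed),
              solution_volume_l = solution_volume_l,
              solution_conc_mg_l = solution_conc_mg_l,
              delta_init = delta_init, epsilon_uptake = epsilon_uptake,
              epsilon_seq_mob = epsilon_seq_mob,
              base_uptake_fraction = base_uptake_fraction,
              fe_uptake_multiplier = fe_uptake_multiplier,
              uptake_jitter = uptake_jitter,
              f_leaf_base = f_leaf_base, fe_fshoot_shift = fe_fshoot_shift,
              f_leaf_jitter = f_leaf_jitter, f_stem_base = f_stem_base,
              f_stem_jitter = f_stem_jitter, d_ls_target = d_ls_target,
              biomass_range_g = biomass_range_g,
              leaf_share_range = leaf_share_range,
              noise_delta_2sd = noise_delta_2sd,
              noise_conc_rel = noise_conc_rel)
  stopifnot(cfg$base_uptake_fraction > 0, cfg$base_uptake_fraction < 1,
            cfg$fe_uptake_multiplier > 0,
            cfg$replicates_analysed <= cfg$replicates_grown,
            cfg$f_leaf_base - cfg$fe_fshoot_shift - cfg$f_leaf_jitter > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a complete hydroponic Cd isotope experiment
#'
#' Generates, for every treatment, a finite Cd reservoir, per-plant uptake
#' fractions (i.i.d. uniform jitter around the treatment mean; hydroponic-Fe
#' treatments scaled up by the renormalised Fe multiplier), a total-plant
#' composition set by the accumulated-product Rayleigh relation at the
#' treatment's remaining fraction, and a leaf/stem/root partition in which the
#' leaf satisfies the sequestration/mobilisation relation exactly, the stem is
#' offset from the leaf by the configured leaf-stem fractionation, and the
#' root closes the isotope mass balance. Organ concentrations are
#' back-computed from organ Cd masses and simulated biomass; Gaussian
#' analytical noise is applied last, to the reported concentrations and delta
#' values only, so the underlying truth stays exactly conservative.
#'
#' @param config a [sim_config()].
#' @return list with `plants` (long measurement table in the `plants.csv`
#'   schema, plus an `analysed` flag), `solutions` (per-treatment reservoir
#'   state: initial Cd, fraction remaining, final delta), and `truth`
#'   (noise-free per-plant table and the generating parameters).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tr <- config$treatments
  n_tr <- nrow(tr)
  reservoir_ug <- config$solution_volume_l * config$solution_conc_mg_l * 1000
  mult <- ifelse(tr$hydro_fe, config$fe_uptake_multiplier, 1)
  rel <- mult / mean(mult)

  ng <- config$replicates_grown
  n_pl <- n_tr * ng

  # per-plant design expansion (treatment-major, replicate-minor order; RNG
  # draws follow this order so a seed fixes the whole experiment)
  tr_idx <- rep(seq_len(n_tr), each = ng)
  rep_id <- rep(seq_len(ng), times = n_tr)
  u <- (config$base_uptake_fraction / ng) * rel[tr_idx] *
    stats::runif(n_pl, 1 - config$uptake_jitter, 1 + config$uptake_jitter)
  u_tr <- as.numeric(rowsum(u, tr_idx))
  f_rem <- 1 - u_tr
  if (any(f_rem <= 0)) stop("simulate_experiment: uptake exceeds reservoir")
  delta_tot_tr <- accumulated_product_delta(config$delta_init,
                                            config$epsilon_uptake, f_rem)
  delta_tot <- delta_tot_tr[tr_idx]
  total_cd <- reservoir_ug * u

  f_leaf <- config$f_leaf_base -
    ifelse(tr$hydro_fe[tr_idx], 0, config$fe_fshoot_shift) +
    stats::runif(n_pl, -config$f_leaf_jitter, config$f_leaf_jitter)
  f_stem <- config$f_stem_base +
    stats::runif(n_pl, -config$f_stem_jitter, config$f_stem_jitter)
  f_root <- 1 - f_leaf - f_stem
  if (any(f_leaf >= 1) || any(f_root <= 0)) {
    stop("simulate_experiment: infeasible organ partition")
  }
  d_leaf <- delta_tot + config$epsilon_seq_mob * log(f_leaf)
  d_stem <- d_leaf - config$d_ls_target
  d_root <- (delta_tot - f_leaf * d_leaf - f_stem * d_stem) / f_root

  total_g <- stats::runif(n_pl, config$biomass_range_g[1], config$biomass_range_g[2])
  leaf_share <- stats::runif(n_pl, config$leaf_share_range[1], config$leaf_share_range[2])
  stem_share <- (1 - leaf_share) * stats::runif(n_pl, 0.4, 0.6)
  mass <- cbind(root = total_g * (1 - leaf_share - stem_share),
                stem = total_g * stem_share, leaf = total_g * leaf_share)
  cd_ug <- cbind(root = f_root, stem = f_stem, leaf = f_leaf) * total_cd
  conc_true <- cd_ug / mass
  delta_true <- cbind(root = d_root, stem = d_stem, leaf = d_leaf)

  conc_obs <- conc_true * (1 + matrix(stats::rnorm(3 * n_pl, 0, config$noise_conc_rel),
                                      n_pl, 3))
  delta_obs <- delta_true + matrix(stats::rnorm(3 * n_pl, 0, config$noise_delta_2sd / 2),
                                   n_pl, 3)

  organ_order <- c("root", "stem", "leaf")
  long <- rep(seq_len(n_pl), each = 3)     # plant index per long row
  oi <- rep(1:3, times = n_pl)             # organ index per long row
  plants <- tibble::tibble(
    treatment_id = tr$treatment_id[tr_idx][long],
    replicate_id = rep_id[long],
    hydro_fe = tr$hydro_fe[tr_idx][long], hydro_zn = tr$hydro_zn[tr_idx][long],
    foliar_fe = tr$foliar_fe[tr_idx][long], foliar_zn = tr$foliar_zn[tr_idx][long],
    organ = organ_order[oi],
    dry_mass_g = mass[cbind(long, oi)],
    conc_mg_per_kg = conc_obs[cbind(long, oi)],
    delta114_permil = delta_obs[cbind(long, oi)],
    two_sd_permil = config$noise_delta_2sd,
    analysed = rep_id[long] <= config$replicates_analysed
  )
  truth_tbl <- tibble::tibble(
    treatment_id = tr$treatment_id[tr_idx], replicate_id = rep_id,
    uptake_fraction = u, total_cd_ug = total_cd, delta_tot = delta_tot,
    f_root = f_root, f_stem = f_stem, f_leaf = f_leaf,
    delta_root = d_root, delta_stem = d_stem, delta_leaf = d_leaf,
    conc_root = conc_true[, "root"], conc_stem = conc_true[, "stem"],
    conc_leaf = conc_true[, "leaf"]
  )
  solutions <- tibble::tibble(
    treatment_id = tr$treatment_id,
    cd_mass_init_ug = reservoir_ug,
    delta_init = config$delta_init,
    f_remaining = f_rem,
    cd_removed_ug = reservoir_ug * u_tr,
    delta_final = config$delta_init + config$epsilon_uptake * log(f_rem)
  )
  list(plants = plants, solutions = solutions,
       truth = list(per_plant = truth_tbl,
                    parameters = unclass(config)[setdiff(names(config), "treatments")]))
}
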