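#' Validate a long per-organ measurement table
#'
#' Checks the `plants.csv` contract: required columns present, numeric types,
#' physically plausible ranges (delta within +/-5 permil, concentrations >= 0,
#' dry masses > 0) and uniqueness of (treatment, replicate, organ). Violations
#' are reported with row numbers; nothing is coerced or repaired.
#'
#' @param plants data frame or path to a CSV file.
#' @return tibble of violations (`row`, `column`, `message`); zero rows when
#'   the table is valid.
#' @export
validate_plants_table <- function(plants) {
  if (is.character(plants)) plants <- utils::read.csv(plants, stringsAsFactors = FALSE)
  required <- c("treatment_id", "replicate_id", "organ", "dry_mass_g",
                "conc_mg_per_kg", "delta114_permil", "two_sd_permil")
  v <- list()
  bad <- function(row, column, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(row = row, column = column,
                                           message = message)
  }
  miss <- setdiff(required, names(plants))
  for (m in miss) bad(NA_integer_, m, "required column missing")
  if (length(miss)) return(dplyr::bind_rows(v))

  num_cols <- c("dry_mass_g", "conc_mg_per_kg", "delta114_permil", "two_sd_permil")
  for (cl in num_cols) {
    if (!is.numeric(plants[[cl]])) bad(NA_integer_, cl, "column must be numeric")
  }
  if (any(!vapply(plants[num_cols], is.numeric, logical(1)))) {
    return(dplyr::bind_rows(v))
  }
  for (i in seq_len(nrow(plants))) {
    if (!plants$organ[i] %in% c("root", "stem", "leaf")) {
      bad(i, "organ", "organ must be root, stem or leaf")
    }
    if (is.na(plants$dry_mass_g[i]) || plants$dry_mass_g[i] <= 0) {
      bad(i, "dry_mass_g", "dry mass must be > 0")
    }
    if (is.na(plants$conc_mg_per_kg[i]) || plants$conc_mg_per_kg[i] < 0) {
      bad(i, "conc_mg_per_kg", "concentration must be >= 0")
    }
    if (!is.na(plants$delta114_permil[i]) && abs(plants$delta114_permil[i]) > 5) {
      bad(i, "delta114_permil", "delta outside +/-5 permil plausibility range")
    }
    if (!is.na(plants$two_sd_permil[i]) && plants$two_sd_permil[i] < 0) {
      bad(i, "two_sd_permil", "2sd must be >= 0")
    }
  }
  key <- paste(plants$treatment_id, plants$replicate_id, plants$organ, sep = "\r")
  dup <- which(duplicated(key))
  for (i in dup) bad(i, "organ", "duplicated (treatment, replicate, organ)")
  if (length(v) == 0) {
    return(tibble::tibble(row = integer(0), column = character(0),
                          message = character(0)))
  }
  dplyr::bind_rows(v)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end on a long per-organ table: validation,
#' per-plant derivation, per-treatment summary, final-solution mass balance
#' and uptake fractionation, forced-origin Rayleigh fits for leaf and shoot
#' sinks, and pooled nonparametric comparisons. Optionally writes
#' `plant_derived.csv`, `treatment_summary.csv`, `rayleigh_fits.json`,
#' `stats.json` and a merged `report.json` (full precision; rounding is left
#' to display layers).
#'
#' @param plants data frame or CSV path in the `plants.csv` schema.
#' @param delta_sol solution delta114Cd (permil), default -0.36.
#' @param solution_cd_ug initial reservoir Cd mass per treatment (ug); default
#'   `solution_volume_l * solution_conc_mg_l * 1000`.
#' @param solution_volume_l,solution_conc_mg_l reservoir geometry used when
#'   `solution_cd_ug` is not given (defaults 3 L, 2.25 mg/L).
#' @param out_dir optional output directory; created if needed.
#' @param stats_variables,stats_factors variables and design factors for the
#'   pooled comparisons (skipped silently for factors that do not split the
#'   data).
#' @return list with `plant_derived`, `treatment_summary`, `grand_means`,
#'   `solutions` (per-treatment mass balance incl. `delta_final` and
#'   `epsilon_uptake`), `rayleigh` (leaf and shoot `rayleigh_fit`s), `stats`
#'   (list of `group_comparison`s), and `files` (paths written, if any).
#' @export
run_pipeline <- function(plants, delta_sol = -0.36, solution_cd_ug = NULL,
                         solution_volume_l = 3, solution_conc_mg_l = 2.25,
                         out_dir = NULL,
                         stats_variables = c("total_cd_ug", "tf_percent",
                                             "f_shoot", "d_sh_tot"),
                         stats_factors = c("hydro_fe", "hydro_zn",
                                           "foliar_fe", "foliar_zn")) {
  if (is.character(plants)) plants <- utils::read.csv(plants, stringsAsFactors = FALSE)
  if (nrow(plants) == 0) stop("run_pipeline: empty input")
  violations <- validate_plants_table(plants)
  if (nrow(violations) > 0) {
    stop("run_pipeline: input table is invalid:\n",
         paste(sprintf("  row %s, %s: %s", violations$row, violations$column,
                       violations$message), collapse = "\n"))
  }
  if (is.null(solution_cd_ug)) {
    solution_cd_ug <- solution_volume_l * solution_conc_mg_l * 1000
  }
  derived <- derive_plants(plants, delta_sol = delta_sol)
  summ <- treatment_summary(plants, delta_sol = delta_sol)
  gm <- grand_means(summ)

  # per-treatment closed-system mass balance and uptake fractionation
  sol_rows <- lapply(split(derived, derived$treatment_id), function(sub) {
    st <- final_solution_state(delta_sol, solution_cd_ug,
                               plant_cd_ug = sub$total_cd_ug,
                               plant_delta = sub$delta_tot)
    tibble::tibble(treatment_id = sub$treatment_id[1],
                   cd_mass_init_ug = solution_cd_ug,
                   cd_removed_ug = st$cd_removed_ug,
                   f_remaining = st$f_remaining,
                   delta_final = st$delta_final,
                   epsilon_uptake = uptake_epsilon(delta_sol, st$delta_final,
                                                   st$f_remaining))
  })
  solutions <- dplyr::bind_rows(sol_rows)

  ok_leaf <- !is.na(derived$f_leaf) & !is.na(derived$d_l_tot) & derived$f_leaf < 1
  ok_shoot <- !is.na(derived$f_shoot) & !is.na(derived$d_sh_tot) & derived$f_shoot < 1
  fits <- list(
    leaf = fit_rayleigh(derived$f_leaf[ok_leaf], derived$d_l_tot[ok_leaf],
                        sink = "leaf"),
    shoot = fit_rayleigh(derived$f_shoot[ok_shoot], derived$d_sh_tot[ok_shoot],
                         sink = "shoot")
  )

  stats_out <- list()
  for (fac in stats_factors) {
    if (!fac %in% names(derived) || length(unique(derived[[fac]])) < 2) next
    for (var in stats_variables) {
      if (!var %in% names(derived)) next
      stats_out[[paste(var, "by", fac)]] <-
        pooled_group_compare(derived, fac, var)
    }
  }

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      path <- file.path(out_dir, name)
      utils::write.csv(df, path, row.names = FALSE)
      path
    }
    files <- c(wr(derived, "plant_derived.csv"),
               wr(summ, "treatment_summary.csv"),
               wr(solutions, "solutions.csv"))
    fit_path <- file.path(out_dir, "rayleigh_fits.json")
    jsonlite::write_json(lapply(fits, unclass), fit_path, auto_unbox = TRUE,
                         digits = NA)
    stats_path <- file.path(out_dir, "stats.json")
    jsonlite::write_json(lapply(stats_out, unclass), stats_path,
                         auto_unbox = TRUE, digits = NA)
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(list(
      n_plants = nrow(derived), n_treatments = nrow(summ),
      delta_sol = delta_sol, solution_cd_ug = solution_cd_ug,
      grand_means = gm,
      epsilon_uptake_mean_abs = mean(abs(solutions$epsilon_uptake)),
      rayleigh = lapply(fits, function(f) list(sink = f$sink,
                                               epsilon = f$epsilon,
                                               n_points = f$n_points,
                                               residual_sd = f$residual_sd)),
      stats = lapply(stats_out, unclass)
    ), report_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, fit_path, stats_path, report_path)
  }

  list(plant_derived = derived, treatment_summary = summ, grand_means = gm,
       solutions = solutions, rayleigh = fits, stats = stats_out,
       files = files)
}
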