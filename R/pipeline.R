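#' Run the full analysis pipeline on a synthetic experiment
#'
#' Executes the whole chain end to end, deterministically for a fixed seed:
#' generate a synthetic experiment, calibrate cell size on the bead
#' standards, estimate per-group C/N biomass from the flow-cytometry table,
#' compute the nitrogen budget (drawdown vs biomass increment, fixation
#' share of Crocosphaera demand), fit a quadratic nutrient forcing to the
#' +NH4 treatment and replay the incubation model under it, fit the
#' Crocosphaera NH4+ uptake maximum back from the observations, and run the
#' three ecosystem competition scenarios. All stage outputs are written
#' under `out_dir` together with a manifest (package version, seed, config
#' hash, file checksums).
#'
#' @param out_dir Output directory.
#' @param seed Master seed for the synthetic experiment.
#' @param config Optional [generator_config()] (its seed is overridden by
#'   `seed` when both are given).
#' @param fit_free,fit_bounds Free parameters and bounds for the fitting
#'   stage (defaults: Crocosphaera `vmax_nh4` in [1, 12]).
#' @param n_starts Multistarts for the fit.
#' @param scenario_t_end Duration of the ecosystem scenarios, days.
#' @return Invisibly, a list with every stage result (`experiment`,
#'   `calibration`, `biomass`, `budget`, `forcing`, `incubation`, `fit`,
#'   `scenarios`, `manifest`).
#' @examples
#' \donttest{
#' res <- run_pipeline(tempfile("croco"), seed = 7)
#' res$budget
#' }
#' @export
run_pipeline <- function(out_dir, seed = 1, config = NULL,
                         fit_free = "Cro.vmax_nh4",
                         fit_bounds = list(Cro.vmax_nh4 = c(1, 12)),
                         n_starts = 6, scenario_t_end = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- config %||% generator_config(seed = seed)
  config$seed <- as.integer(seed)

  # stage 1: generate
  experiment <- generate_experiment(config)
  write_experiment(experiment, file.path(out_dir, "data"))

  # stage 2: size calibration + biomass
  cal <- calibrate_size(experiment$beads)
  biomass <- estimate_biomass(experiment$fcm, cal)
  readr::write_csv(
    dplyr::select(biomass, "day", "treatment", "replicate", "group",
                  "c_nmol_l", "n_nmol_l"),
    file.path(out_dir, "biomass.csv"))

  # stage 3: nitrogen budget
  budget <- nitrogen_budget(experiment$nutrients, biomass,
                            arr = experiment$arr,
                            detection_limits = config$detection_limits[c("nh4", "no3")],
                            cro_mortality = config$groups$Cro$mortality)
  readr::write_csv(budget, file.path(out_dir, "budget.csv"))

  # stage 4: forcing fit (+NH4 treatment) and incubation replay
  nut_nh4 <- dplyr::filter(experiment$nutrients, .data$treatment == "nh4")
  f_nh4 <- fit_nutrient_forcing(
    dplyr::filter(nut_nh4, .data$nutrient == "nh4"),
    detection_limit = config$detection_limits[["nh4"]])
  f_no3 <- fit_nutrient_forcing(
    dplyr::filter(nut_nh4, .data$nutrient == "no3"),
    detection_limit = config$detection_limits[["no3"]])
  forcing <- as_forcing(f_nh4, f_no3)

  obs <- biomass |>
    dplyr::filter(.data$treatment == "nh4") |>
    dplyr::select("day", "group", "replicate", "n_nmol_l")
  init <- obs |>
    dplyr::filter(.data$day == 0) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n0 = mean(.data$n_nmol_l), .groups = "drop")
  incubation <- run_incubation(config$groups[init$group], forcing,
                               setNames(init$n0, init$group), t_end = max(obs$day))
  write_trajectory(incubation, file.path(out_dir, "incubation.csv"))

  # stage 5: parameter fit
  fit <- fit_parameters(obs, forcing, config$groups, free = fit_free,
                        bounds = fit_bounds, n_starts = n_starts, seed = seed)
  jsonlite::write_json(
    list(estimates = tidy(fit), glance = glance(fit),
         starts = fit$starts, seed = seed, bounds = fit_bounds),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")

  # stage 6: ecosystem scenarios
  scenarios <- scenario_suite(t_end = scenario_t_end)
  write_trajectory(scenarios, file.path(out_dir, "scenarios.csv"))

  outputs <- c("data/nutrients.csv", "data/fcm.csv", "data/beads.csv",
               "data/arr.csv", "biomass.csv", "budget.csv",
               "incubation.csv", "fit.json", "scenarios.csv")
  manifest <- list(
    package_version = as.character(packageVersion("crococompete")),
    seed = seed,
    config_hash = rlang::hash(config),
    files = as.list(unname(tools::md5sum(file.path(out_dir, outputs)))) |>
      setNames(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(experiment = experiment, calibration = cal,
                 biomass = biomass, budget = budget, forcing = forcing,
                 incubation = incubation, fit = fit, scenarios = scenarios,
                 manifest = manifest))
}
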