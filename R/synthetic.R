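#' Configuration for the synthetic incubation-experiment generator
#'
#' Describes a complete simulated bottle experiment: four treatments
#' (control, +NH4 100 nM, +NO3 100 nM, +P 10 nM as a no-N-effect arm),
#' daily sampling over days 0–3 in triplicate, four phytoplankton groups
#' with their own uptake kinetics and size distributions, a multiplicative
#' lognormal noise model, and analytical detection limits (NH4+ 6,
#' NO3-+NO2- 3, SRP 3 nM) below which concentrations are flagged censored.
#'
#' Two "tunable truths" shape the budgets: `sink_fraction` is the share of
#' nutrient drawdown that does not appear as particulate biomass (luxury
#' uptake / estimation gap; default 0.5, so biomass explains about half of
#' the drawdown), and `fixation_fraction` is the share of Crocosphaera's
#' gross N demand met by N2 fixation (default 0.05, within the observed
#' 0.5–12.7 percent range for unamended water).
#'
#' All values are package defaults for a plausible oligotrophic surface
#' community, not field measurements.
#'
#' @param seed Master seed; every table draws from its own stream split
#'   from it, so adding a table never perturbs existing draws.
#' @param days Sampling days.
#' @param replicates Bottles per treatment.
#' @param groups Named list of four [phyto_params()] (true kinetics).
#' @param size_median_um Named vector of true median cell diameters, um.
#' @param size_sigma_log Lognormal sigma of the within-population size
#'   distribution (affects reported median FLS noise only).
#' @param abundance0_cells_ml Named vector of day-0 abundances, cells mL^-1.
#' @param fls_coef,fls_exp True bead/cell power law `FLS = coef * d^exp`.
#' @param ambient_nh4,ambient_no3 Ambient concentrations, nmol L^-1.
#' @param amendments Named list of `c(nh4, no3)` additions per treatment,
#'   nmol L^-1.
#' @param noise_sigma Lognormal sigma for abundances and concentrations.
#' @param fls_noise_sigma Lognormal sigma for median-FLS readings.
#' @param bead_noise_sigma Lognormal sigma for bead FLS readings.
#' @param sink_fraction Fraction of drawdown not appearing in biomass
#'   (0 <= s < 1).
#' @param fixation_fraction Target share of Crocosphaera gross N demand met
#'   by fixation (sets the true acetylene-reduction rates).
#' @param detection_limits Named vector, nmol L^-1.
#' @param dt Integration step of the truth simulation, days.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    seed = 1,
    days = 0:3,
    replicates = 3,
    groups = default_generator_groups(),
    size_median_um = c(Pro = 0.6, Syn = 1.0, Cro = 3.5, PicoE = 2.0),
    size_sigma_log = 0.1,
    abundance0_cells_ml = c(Pro = 8e4, Syn = 5e3, Cro = 300, PicoE = 1e3),
    fls_coef = 50, fls_exp = 2.5,
    ambient_nh4 = 8, ambient_no3 = 15,
    amendments = list(control = c(nh4 = 0, no3 = 0),
                      nh4 = c(nh4 = 100, no3 = 0),
                      no3 = c(nh4 = 0, no3 = 100),
                      p = c(nh4 = 0, no3 = 0)),
    noise_sigma = 0.10,
    fls_noise_sigma = 0.05,
    bead_noise_sigma = 0.02,
    sink_fraction = 0.5,
    fixation_fraction = 0.05,
    detection_limits = c(nh4 = 6, no3 = 3, srp = 3),
    dt = 0.005) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            replicates >= 1, length(days) >= 2,
            sink_fraction >= 0, sink_fraction < 1,
            fixation_fraction >= 0,
            noise_sigma >= 0, all(detection_limits > 0), dt > 0)
  gnames <- names(groups)
  stopifnot(!is.null(gnames),
            setequal(gnames, names(size_median_um)),
            setequal(gnames, names(abundance0_cells_ml)))
  structure(
    list(seed = as.integer(seed), days = days, replicates = replicates,
         groups = groups, size_median_um = size_median_um,
         size_sigma_log = size_sigma_log,
         abundance0_cells_ml = abundance0_cells_ml,
         fls_coef = fls_coef, fls_exp = fls_exp,
         ambient_nh4 = ambient_nh4, ambient_no3 = ambient_no3,
         amendments = amendments, noise_sigma = noise_sigma,
         fls_noise_sigma = fls_noise_sigma,
         bead_noise_sigma = bead_noise_sigma,
         sink_fraction = sink_fraction,
         fixation_fraction = fixation_fraction,
         detection_limits = detection_limits, dt = dt),
    class = "generator_config"
  )
}

#' Default true kinetics of the four generated groups
#'
#' Crocosphaera uses the package default Cro parameters; the three
#' non-diazotroph groups are variations on the "other phytoplankton"
#' defaults (lower maximum uptake, lower half-saturation).
#'
#' @return Named list of [phyto_params()] (`Pro`, `Syn`, `Cro`, `PicoE`).
#' @export
default_generator_groups <- function() {
  list(
    Pro = phyto_params("Pro", vmax_nh4 = 1.1, vmax_no3 = 0.8,
                       k_nh4 = 20, k_no3 = 20, mortality = 0.1),
    Syn = phyto_params("Syn", vmax_nh4 = 1.0, vmax_no3 = 0.7,
                       k_nh4 = 25, k_no3 = 25, mortality = 0.1),
    Cro = default_phyto_params()$cro,
    PicoE = phyto_params("PicoE", vmax_nh4 = 0.9, vmax_no3 = 0.6,
                         k_nh4 = 30, k_no3 = 30, mortality = 0.1)
  )
}

# per-table RNG sub-seed, kept inside 32-bit integer range
.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + offset * 7919) %% 2147483647)
}

# true per-cell properties from the config's size medians and power law
.per_cell_truth <- function(config, conversions = default_conversions()) {
  purrr::imap_dfr(config$size_median_um[names(config$groups)], function(d, g) {
    fls <- config$fls_coef * d^config$fls_exp
    vol <- pi / 6 * d^3
    cfg_conv <- conversions[[g]]
    c_fg <- carbon_per_cell(cfg_conv, vol)
    tibble::tibble(group = g, diameter_um = d, fls = fls, volume_um3 = vol,
                   c_fg_cell = c_fg,
                   n_fmol_cell = nitrogen_per_cell(cfg_conv, c_fg))
  })
}

# coupled truth simulation for one treatment: 4 phyto pools + 2 nutrients,
# nutrients drained at uptake / (1 - sink_fraction); returns daily states
# plus integrated per-group uptake and mortality loss
.simulate_treatment <- function(config, amendment) {
  groups <- config$groups
  ng <- length(groups)
  m <- vapply(groups, `[[`, numeric(1), "mortality")
  drain <- 1 / (1 - config$sink_fraction)

  # Nutrient balance: net community assimilation (gross uptake minus
  # remineralized mortality) leaves the dissolved pool, inflated by the
  # unexplained-sink factor and split across NH4/NO3 by gross-uptake share.
  # This makes biomass increment = (1 - sink) * drawdown an exact identity
  # of the pre-noise truth, for any mortality.
  deriv <- function(y) {
    N <- y[seq_len(ng)]
    nh4 <- max(y[ng + 1L], 0); no3 <- max(y[ng + 2L], 0)
    up_nh4 <- vapply(groups, function(p)
      p$vmax_nh4 * nh4 / (nh4 + p$k_nh4), numeric(1)) * N
    up_no3 <- vapply(groups, function(p)
      p$vmax_no3 * no3 / (no3 + p$k_no3), numeric(1)) * N
    gross <- sum(up_nh4) + sum(up_no3)
    w_nh4 <- if (gross > 0) sum(up_nh4) / gross else 0.5
    net <- gross - sum(m * N)
    c(up_nh4 + up_no3 - m * N,
      -w_nh4 * net * drain, -(1 - w_nh4) * net * drain,
      up_nh4 + up_no3,   # cumulative gross uptake per group
      m * N)             # cumulative mortality loss per group
  }

  pc <- .per_cell_truth(config)
  n_fmol <- setNames(pc$n_fmol_cell, pc$group)[names(groups)]
  n0 <- config$abundance0_cells_ml[names(groups)] * 1000 * n_fmol / 1e6
  y <- c(unname(n0),
         config$ambient_nh4 + amendment[["nh4"]],
         config$ambient_no3 + amendment[["no3"]],
         rep(0, 2 * ng))
  t_end <- max(config$days); dt <- config$dt
  times <- seq(0, t_end, by = dt)
  keep_idx <- vapply(config$days, function(d) which.min(abs(times - d)),
                     integer(1))
  out <- matrix(NA_real_, length(config$days), length(y))
  if (1L %in% keep_idx) out[match(1L, keep_idx), ] <- y
  for (s in seq_len(length(times) - 1L)) {
    h <- times[s + 1L] - times[s]
    k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[seq_len(ng + 2L)] <- pmax(y[seq_len(ng + 2L)], 0)
    hit <- match(s + 1L, keep_idx)
    if (!is.na(hit)) out[hit, ] <- y
  }
  gname <- names(groups)
  list(
    pools = tibble::tibble(
      day = rep(config$days, ng),
      group = rep(gname, each = length(config$days)),
      n_nmol_l = as.vector(out[, seq_len(ng)])),
    nutrients = tibble::tibble(
      day = rep(config$days, 2L),
      nutrient = rep(c("nh4", "no3"), each = length(config$days)),
      conc_nmol_l = as.vector(out[, ng + 1:2])),
    uptake = setNames(out[length(config$days), ng + 2L + seq_len(ng)], gname),
    mortality_loss = setNames(out[length(config$days), 2L * ng + 2L + seq_len(ng)],
                              gname)
  )
}

#' Generate a complete synthetic incubation experiment
#'
#' Forward-simulates the true cellular-N pools of all four groups in every
#' treatment with the incubation model, draining the nutrient pools by net
#' community assimilation (gross uptake minus remineralized mortality)
#' inflated by the unexplained-sink factor, so that the biomass increment
#' equals `(1 - sink_fraction)` times the drawdown exactly in the pre-noise
#' truth; converts true
#' pools to flow-cytometry observables (abundance, median FLS) via the true
#' per-cell size/carbon/nitrogen chain; sets true acetylene-reduction rates
#' from the target fixation share of Crocosphaera's gross demand; applies
#' multiplicative lognormal noise; and censors nutrient values below the
#' detection limits (value retained, `below_detection` flag set).
#'
#' Regenerating with the same config is deterministic (byte-identical
#' written files); each output table uses its own random stream split from
#' the master seed.
#'
#' @param config A [generator_config()].
#' @return A `croco_experiment`: list with tibbles `nutrients`, `fcm`,
#'   `beads`, `arr`, a `truth` list (true parameters, per-cell properties,
#'   pre-noise pool and nutrient series, per-treatment budget truths) and
#'   the `config`. Write to disk with [write_experiment()].
#' @examples
#' exp <- generate_experiment(generator_config(seed = 42))
#' dplyr::filter(exp$nutrients, treatment == "nh4", nutrient == "nh4")
#' @export
generate_experiment <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  treatments <- names(config$amendments)
  pc <- .per_cell_truth(config)

  sims <- purrr::map(config$amendments, ~ .simulate_treatment(config, .x))

  truth_pools <- purrr::imap_dfr(sims, ~ dplyr::mutate(.x$pools, treatment = .y))
  truth_nut <- purrr::imap_dfr(sims, ~ dplyr::mutate(.x$nutrients, treatment = .y))

  # true per-treatment budget
  truth_budget <- purrr::imap_dfr(sims, function(s, tr) {
    draw <- s$nutrients |>
      dplyr::group_by(.data$nutrient) |>
      dplyr::summarise(d = dplyr::first(.data$conc_nmol_l) -
                         dplyr::last(.data$conc_nmol_l), .groups = "drop")
    inc <- s$pools |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(i = dplyr::last(.data$n_nmol_l) -
                         dplyr::first(.data$n_nmol_l), .groups = "drop")
    cro_demand <- unname(s$uptake["Cro"])
    tibble::tibble(
      treatment = tr,
      drawdown_nmol_l = sum(draw$d),
      biomass_increment_nmol_l = sum(inc$i),
      uptake_nmol_l = sum(s$uptake),
      ratio = sum(inc$i) / sum(draw$d),
      cro_demand_nmol_l = cro_demand,
      fixation_n_nmol_l = config$fixation_fraction * cro_demand,
      pct_fixation = 100 * config$fixation_fraction
    )
  })

  span <- max(config$days) - min(config$days)
  reps <- seq_len(config$replicates)
  ln_noise <- function(n, sigma) exp(rnorm(n, 0, sigma))

  # --- nutrients table (own stream) ---
  set.seed(.sub_seed(config$seed, 1L))
  nutrients <- truth_nut |>
    tidyr::crossing(replicate = reps) |>
    dplyr::arrange(.data$treatment, .data$day, .data$nutrient, .data$replicate) |>
    dplyr::mutate(
      conc_nmol_l = .data$conc_nmol_l * ln_noise(dplyr::n(), config$noise_sigma),
      below_detection = .data$conc_nmol_l <
        unname(config$detection_limits[.data$nutrient])) |>
    dplyr::select("day", "treatment", "replicate", "nutrient",
                  "conc_nmol_l", "below_detection")

  # --- fcm table (own stream) ---
  set.seed(.sub_seed(config$seed, 2L))
  fcm <- truth_pools |>
    dplyr::left_join(pc, by = "group") |>
    dplyr::mutate(abundance_true = .data$n_nmol_l * 1e6 / .data$n_fmol_cell / 1000) |>
    tidyr::crossing(replicate = reps) |>
    dplyr::arrange(.data$treatment, .data$day, .data$group, .data$replicate) |>
    dplyr::mutate(
      abundance_cells_per_ml = .data$abundance_true *
        ln_noise(dplyr::n(), config$noise_sigma),
      median_fls = .data$fls * ln_noise(dplyr::n(), config$fls_noise_sigma)) |>
    dplyr::select("day", "treatment", "replicate", "group",
                  "abundance_cells_per_ml", "median_fls")

  # --- beads table (own stream) ---
  set.seed(.sub_seed(config$seed, 3L))
  beads <- generate_bead_standards(config, .seeded = FALSE)

  # --- arr table (own stream) ---
  set.seed(.sub_seed(config$seed, 4L))
  arr <- truth_budget |>
    dplyr::mutate(ethylene_true = .data$fixation_n_nmol_l / span / 2 * 4) |>
    dplyr::select("treatment", "ethylene_true") |>
    tidyr::crossing(day = config$days[-1], replicate = reps) |>
    dplyr::arrange(.data$treatment, .data$day, .data$replicate) |>
    dplyr::mutate(ethylene_nmol_l_d = .data$ethylene_true *
                    ln_noise(dplyr::n(), config$noise_sigma)) |>
    dplyr::select("day", "treatment", "replicate", "ethylene_nmol_l_d")

  truth <- list(
    seed = config$seed,
    groups = purrr::map(config$groups, unclass),
    per_cell = pc,
    pools = truth_pools,
    nutrients = truth_nut,
    budget = truth_budget,
    sink_fraction = config$sink_fraction,
    fixation_fraction = config$fixation_fraction,
    fls_law = c(coef = config$fls_coef, exp = config$fls_exp)
  )
  structure(list(nutrients = nutrients, fcm = fcm, beads = beads, arr = arr,
                 truth = truth, config = config),
            class = "croco_experiment")
}

#' Generate bead calibration standards
#'
#' Emits the five canonical monodisperse polystyrene bead diameters (1.75,
#' 2.0, 3.0, 6.0, 10 um) with forward-scatter values drawn from the
#' generator's true power law plus multiplicative lognormal noise.
#'
#' @param config A [generator_config()].
#' @param .seeded Set the bead stream's seed internally (default); callers
#'   that manage streams themselves pass `FALSE`.
#' @return A tibble with columns `diameter_um`, `fls`.
#' @export
generate_bead_standards <- function(config = generator_config(),
                                    .seeded = TRUE) {
  if (.seeded) set.seed(.sub_seed(config$seed, 3L))
  d <- c(1.75, 2.0, 3.0, 6.0, 10.0)
  tibble::tibble(
    diameter_um = d,
    fls = config$fls_coef * d^config$fls_exp *
      exp(rnorm(length(d), 0, config$bead_noise_sigma))
  )
}

#' Deterministic ecosystem-scenario fixture with provenance
#'
#' Wraps [run_ecosystem_scenario()] for one of the canonical scenarios
#' (`"A"`, `"B"`, `"C"`) and returns the trajectory together with the truth
#' (parameters, nutrient regime, fixation flag) for use as a test fixture.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param cro,oth,zoo Parameter objects (defaults as in [scenario_suite()]).
#' @param t_end,dt Duration and step, days.
#' @return List with elements `trajectory` and `truth`.
#' @export
generate_ecosystem_truth <- function(scenario = c("A", "B", "C"),
                                     cro = default_phyto_params()$cro,
                                     oth = default_phyto_params()$oth,
                                     zoo = zoo_params(),
                                     t_end = 10, dt = 0.01) {
  scenario <- match.arg(scenario)
  cfg <- switch(scenario,
                A = list(nut = nutrient_pair(100, 100), fix = FALSE),
                B = list(nut = nutrient_pair(1, 1), fix = FALSE),
                C = list(nut = nutrient_pair(1, 1), fix = TRUE))
  tr <- run_ecosystem_scenario(cfg$nut, cro, oth, zoo,
                               fixation_enabled = cfg$fix,
                               t_end = t_end, dt = dt, label = scenario)
  list(trajectory = tr,
       truth = list(scenario = scenario, nutrients = unclass(cfg$nut),
                    fixation_enabled = cfg$fix,
                    cro = unclass(cro), oth = unclass(oth),
                    zoo = unclass(zoo), t_end = t_end, dt = dt))
}

#' Write a synthetic experiment to disk
#'
#' Writes `nutrients.csv`, `fcm.csv`, `beads.csv`, `arr.csv`, a
#' `truth.json` sidecar and a `manifest.json` (config hash, package
#' version, file checksums) into `dir`.
#'
#' @param experiment A `croco_experiment` from [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "croco_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("nutrients", "fcm", "beads", "arr")
  for (tb in tables)
    readr::write_csv(experiment[[tb]], file.path(dir, paste0(tb, ".csv")))
  jsonlite::write_json(
    purrr::map(experiment$truth, function(x)
      if (inherits(x, "tbl_df")) x else x),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  manifest <- list(
    package_version = as.character(packageVersion("crococompete")),
    seed = experiment$config$seed,
    config_hash = rlang::hash(experiment$config),
    files = as.list(tools::md5sum(file.path(dir, paste0(tables, ".csv"))))
  )
  names(manifest$files) <- paste0(tables, ".csv")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
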