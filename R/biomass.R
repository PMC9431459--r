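#' Calibrate cell size against bead standards
#'
#' Fits an ordinary least-squares line to log(diameter) versus log(forward
#' light scatter) over a set of monodisperse polystyrene bead standards
#' (1.75–10 um in the canonical set). The calibration is later inverted to
#' assign a diameter to each cell population from its median FLS. The valid
#' FLS range is stored; extrapolation beyond it is allowed but flagged,
#' because Prochlorococcus scatters below the smallest bead.
#'
#' @param standards A data frame with columns `diameter_um` (> 0) and `fls`
#'   (> 0), at least two distinct diameters.
#' @return An object of class `size_calibration`: slope and intercept of
#'   `log(diameter) = intercept + slope * log(fls)`, the valid FLS range and
#'   the fit.
#' @examples
#' beads <- tibble::tibble(diameter_um = c(1.75, 2, 3, 6, 10),
#'                         fls = 50 * c(1.75, 2, 3, 6, 10)^2.5)
#' calibrate_size(beads)
#' @export
calibrate_size <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("diameter_um", "fls") %in% names(standards)))
  d <- dplyr::as_tibble(standards)
  if (any(d$diameter_um <= 0) || any(d$fls <= 0))
    stop("bead diameters and FLS must be > 0", call. = FALSE)
  if (length(unique(d$diameter_um)) < 2L)
    stop("need >= 2 distinct bead diameters for a size calibration",
         call. = FALSE)
  fit <- stats::lm(log(diameter_um) ~ log(fls), data = d)
  structure(
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         fls_range = range(d$fls), fit = fit, n = nrow(d)),
    class = "size_calibration"
  )
}

#' @export
print.size_calibration <- function(x, ...) {
  cat(sprintf("<size_calibration> log(d) = %.4g + %.4g log(FLS), valid FLS [%.4g, %.4g], n = %d\n",
              x$intercept, x$slope, x$fls_range[1], x$fls_range[2], x$n))
  invisible(x)
}

#' Convert forward scatter to cell volume
#'
#' Applies the size calibration to get a diameter, then assumes spherical
#' cells: `V = pi/6 * d^3`. FLS values outside the calibration's valid range
#' produce an extrapolation warning but still return a value.
#'
#' @param cal A [calibrate_size()] result.
#' @param fls Forward-scatter values (> 0); vectorised.
#' @return Cell volume(s), um^3.
#' @export
fls_to_volume <- function(cal, fls) {
  stopifnot(inherits(cal, "size_calibration"))
  if (!is.numeric(fls) || any(fls <= 0, na.rm = TRUE))
    stop("fls must be > 0", call. = FALSE)
  outside <- fls < cal$fls_range[1] | fls > cal$fls_range[2]
  if (any(outside, na.rm = TRUE))
    warning(sum(outside, na.rm = TRUE),
            " FLS value(s) outside the bead calibration range; extrapolating",
            call. = FALSE)
  d <- exp(cal$intercept + cal$slope * log(fls))
  pi / 6 * d^3
}

#' Group-specific carbon conversion
#'
#' Describes how a group's cell volume maps to cellular carbon:
#' `"volumetric"` uses a constant carbon density (235 fg C um^-3 for the
#' cyanobacteria Prochlorococcus, Synechococcus and Crocosphaera);
#' `"strathmann"` uses the modified Strathmann power law
#' `log10 C(pg) = slope * log10 V(um^3) + intercept` (0.94 and -0.6 for
#' picoeukaryotes). `cn_ratio` is the molar C:N ratio used to convert C to N.
#'
#' @param group Group label.
#' @param model `"volumetric"` or `"strathmann"`.
#' @param factor Carbon density, fg C um^-3 (volumetric model).
#' @param slope,intercept Log10-scale coefficients (strathmann model).
#' @param cn_ratio Molar C:N ratio (> 0).
#' @return An object of class `group_conversion`.
#' @export
group_conversion <- function(group, model = c("volumetric", "strathmann"),
                             factor = 235, slope = 0.94, intercept = -0.6,
                             cn_ratio) {
  model <- match.arg(model)
  stopifnot(is.numeric(cn_ratio), cn_ratio > 0)
  if (model == "volumetric") stopifnot(is.numeric(factor), factor > 0)
  else stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(group = group, model = model, factor = factor,
                 slope = slope, intercept = intercept,
                 cn_ratio = as.numeric(cn_ratio)),
            class = "group_conversion")
}

#' Default carbon/nitrogen conversions for the four groups
#'
#' Volumetric 235 fg C um^-3 for Prochlorococcus, Synechococcus and
#' Crocosphaera; modified Strathmann (0.94, -0.6) for picoeukaryotes.
#' Molar C:N ratios 9.1, 8.6, 8.7 and 6.6 respectively.
#'
#' @return Named list of [group_conversion()] objects
#'   (`Pro`, `Syn`, `Cro`, `PicoE`).
#' @export
default_conversions <- function() {
  list(
    Pro = group_conversion("Pro", "volumetric", factor = 235, cn_ratio = 9.1),
    Syn = group_conversion("Syn", "volumetric", factor = 235, cn_ratio = 8.6),
    Cro = group_conversion("Cro", "volumetric", factor = 235, cn_ratio = 8.7),
    PicoE = group_conversion("PicoE", "strathmann", slope = 0.94,
                             intercept = -0.6, cn_ratio = 6.6)
  )
}

#' Cellular carbon from cell volume
#'
#' Volumetric model: `C = factor * V` (fg). Strathmann model:
#' `log10 C(pg) = slope * log10 V + intercept`, converted to fg at the
#' boundary (the formula itself yields pg; the package unit is fg).
#'
#' @param conversion A [group_conversion()].
#' @param volume Cell volume(s), um^3 (> 0).
#' @return Carbon per cell, fg C.
#' @export
carbon_per_cell <- function(conversion, volume) {
  stopifnot(inherits(conversion, "group_conversion"))
  if (!is.numeric(volume) || any(volume <= 0, na.rm = TRUE))
    stop("volume must be > 0", call. = FALSE)
  if (conversion$model == "volumetric") conversion$factor * volume
  else 1000 * 10^(conversion$slope * log10(volume) + conversion$intercept)
}

#' Cellular nitrogen from cellular carbon
#'
#' Converts fg C to fmol C at 12.011 g mol^-1 and divides by the group's
#' molar C:N ratio.
#'
#' @param conversion A [group_conversion()].
#' @param carbon Carbon per cell, fg C (>= 0).
#' @return Nitrogen per cell, fmol N.
#' @export
nitrogen_per_cell <- function(conversion, carbon) {
  stopifnot(inherits(conversion, "group_conversion"))
  if (!is.numeric(carbon) || any(carbon < 0, na.rm = TRUE))
    stop("carbon must be >= 0", call. = FALSE)
  if (conversion$cn_ratio <= 0) stop("cn_ratio must be > 0", call. = FALSE)
  (carbon / C_MOLAR_MASS) / conversion$cn_ratio
}

#' Estimate population C and N biomass from flow-cytometry observations
#'
#' The chain per observation: median FLS -> diameter (bead calibration) ->
#' spherical volume -> carbon per cell (group conversion) -> nitrogen per
#' cell (C:N) -> population biomass (x abundance). Unit conversions are
#' explicit: cells mL^-1 -> cells L^-1 (x1000), fmol -> nmol (/1e6).
#'
#' @param fcm A data frame with columns `group`, `abundance_cells_per_ml`,
#'   `median_fls`, plus any identifier columns (`day`, `treatment`,
#'   `replicate`, ...) which are carried through.
#' @param cal A [calibrate_size()] result.
#' @param conversions Named list of [group_conversion()] covering every
#'   group present; default [default_conversions()].
#' @return The input tibble with added columns `volume_um3`,
#'   `c_fg_cell`, `n_fmol_cell`, `c_nmol_l`, `n_nmol_l`.
#' @export
estimate_biomass <- function(fcm, cal, conversions = default_conversions()) {
  stopifnot(is.data.frame(fcm),
            all(c("group", "abundance_cells_per_ml", "median_fls") %in% names(fcm)))
  if (any(fcm$abundance_cells_per_ml < 0, na.rm = TRUE))
    stop("abundances must be >= 0", call. = FALSE)
  missing_conv <- setdiff(unique(fcm$group), names(conversions))
  if (length(missing_conv))
    stop("no conversion for group(s): ", paste(missing_conv, collapse = ", "),
         call. = FALSE)
  d <- dplyr::as_tibble(fcm)
  d$volume_um3 <- fls_to_volume(cal, d$median_fls)
  d <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      c_fg_cell = carbon_per_cell(conversions[[dplyr::cur_group()$group]],
                                  .data$volume_um3),
      n_fmol_cell = nitrogen_per_cell(conversions[[dplyr::cur_group()$group]],
                                      .data$c_fg_cell)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      # cells/mL * 1000 = cells/L; fg C / 12.011 = fmol C; fmol / 1e6 = nmol
      c_nmol_l = .data$abundance_cells_per_ml * 1000 *
        (.data$c_fg_cell / C_MOLAR_MASS) / 1e6,
      n_nmol_l = .data$abundance_cells_per_ml * 1000 *
        .data$n_fmol_cell / 1e6
    )
  d
}

#' Convert an acetylene-reduction (ethylene) rate to fixed nitrogen
#'
#' The acetylene reduction assay measures nitrogenase activity as ethylene
#' production; a molar ratio of 4 mol ethylene per mol N2 converts it to
#' fixation. By default the result is in N atoms (2 per N2), the unit in
#' which the fixation share of N demand is computed; `as = "n2"` returns
#' mol N2.
#'
#' @param ethylene_rate Ethylene production, nmol C2H4 L^-1 d^-1 (>= 0);
#'   vectorised.
#' @param as `"n_atoms"` (default) or `"n2"`.
#' @return Fixed nitrogen, nmol N L^-1 d^-1 (or nmol N2 L^-1 d^-1).
#' @export
ethylene_to_fixed_n <- function(ethylene_rate, as = c("n_atoms", "n2")) {
  as <- match.arg(as)
  if (!is.numeric(ethylene_rate) || any(ethylene_rate < 0, na.rm = TRUE))
    stop("ethylene_rate must be >= 0", call. = FALSE)
  n2 <- ethylene_rate / 4
  if (as == "n2") n2 else 2 * n2
}

#' Share of nitrogen demand met by N2 fixation
#'
#' N demand over an interval is gross N assimilation: the net biomass-N
#' increment plus mortality losses (`integral of m * N dt`). The fixation
#' share is `100 * fixation_n / demand`. Values above 100 percent are
#' reported but flagged via a warning; non-positive demand with positive
#' fixation is undefined and returns `NA` with a warning.
#'
#' @param delta_biomass_n Net biomass-N increment over the interval,
#'   nmol N L^-1.
#' @param mortality_loss_n Mortality loss over the interval, nmol N L^-1
#'   (>= 0). Default 0 gives the net-increment-only variant.
#' @param fixation_n Fixation-derived N input over the interval,
#'   nmol N L^-1 (>= 0).
#' @return Percent of demand met by fixation.
#' @export
fixation_fraction_of_demand <- function(delta_biomass_n, mortality_loss_n = 0,
                                        fixation_n) {
  stopifnot(is.numeric(delta_biomass_n), is.numeric(mortality_loss_n),
            is.numeric(fixation_n), all(fixation_n >= 0),
            all(mortality_loss_n >= 0))
  demand <- delta_biomass_n + mortality_loss_n
  out <- 100 * fixation_n / demand
  bad <- demand <= 0
  if (any(bad & fixation_n > 0)) {
    warning("non-positive N demand with positive fixation: fraction undefined",
            call. = FALSE)
    out[bad] <- NA_real_
  } else if (any(bad)) {
    out[bad] <- NA_real_
  }
  if (any(out > 100, na.rm = TRUE))
    warning("fixation exceeds estimated N demand (> 100%)", call. = FALSE)
  out
}

#' Nitrogen budget: nutrient drawdown versus biomass increment
#'
#' For each treatment over the interval `day_from -> day_to`, computes the
#' combined-nitrogen drawdown (NH4+ plus NO3-, replicate means), the total
#' biomass-N increment summed over groups, their ratio, and — when
#' acetylene-reduction rates are supplied — fixation-derived N and the
#' percent of Crocosphaera's N demand it meets.
#'
#' Censored nutrient values (below the detection limit) are replaced by
#' half the detection limit before differencing, and flagged in
#' `endpoint_censored`.
#'
#' @param nutrients Data frame: `day`, `treatment`, `replicate`, `nutrient`
#'   (`"nh4"`/`"no3"`), `conc_nmol_l`, optional `below_detection`.
#' @param biomass Data frame as returned by [estimate_biomass()] (needs
#'   `day`, `treatment`, `replicate`, `group`, `n_nmol_l`).
#' @param arr Optional data frame: `day`, `treatment`, `replicate`,
#'   `ethylene_nmol_l_d`.
#' @param day_from,day_to Interval endpoints (days present in the data).
#' @param detection_limits Named vector of detection limits, nmol L^-1.
#' @param cro_mortality Linear mortality rate of Crocosphaera used for the
#'   gross-demand correction, d^-1.
#' @param demand Demand definition: `"gross"` (increment + mortality loss,
#'   default) or `"net"` (increment only).
#' @return A tibble, one row per treatment: `drawdown_nmol_l`,
#'   `biomass_increment_nmol_l`, `ratio`, `endpoint_censored`, and (with
#'   `arr`) `fixation_n_nmol_l`, `cro_demand_nmol_l`, `pct_fixation`.
#' @export
nitrogen_budget <- function(nutrients, biomass, arr = NULL,
                            day_from = NULL, day_to = NULL,
                            detection_limits = c(nh4 = 6, no3 = 3),
                            cro_mortality = 0.1,
                            demand = c("gross", "net")) {
  demand <- match.arg(demand)
  stopifnot(is.data.frame(nutrients), is.data.frame(biomass))
  need_n <- c("day", "treatment", "replicate", "nutrient", "conc_nmol_l")
  if (!all(need_n %in% names(nutrients)))
    stop("nutrients must have columns: ", paste(need_n, collapse = ", "),
         call. = FALSE)
  need_b <- c("day", "treatment", "replicate", "group", "n_nmol_l")
  if (!all(need_b %in% names(biomass)))
    stop("biomass must have columns: ", paste(need_b, collapse = ", "),
         call. = FALSE)
  day_from <- day_from %||% min(nutrients$day)
  day_to <- day_to %||% max(nutrients$day)
  if (!all(c(day_from, day_to) %in% nutrients$day) ||
      !all(c(day_from, day_to) %in% biomass$day))
    stop("interval endpoints not present in both tables", call. = FALSE)
  if (!setequal(unique(nutrients$treatment), unique(biomass$treatment)))
    stop("nutrient and biomass tables cover different treatments",
         call. = FALSE)

  nut <- dplyr::as_tibble(nutrients)
  if (!"below_detection" %in% names(nut))
    nut$below_detection <- nut$conc_nmol_l <
      unname(detection_limits[nut$nutrient])
  nut <- nut |>
    dplyr::mutate(conc_used = ifelse(.data$below_detection,
                                     unname(detection_limits[.data$nutrient]) / 2,
                                     .data$conc_nmol_l)) |>
    dplyr::filter(.data$day %in% c(day_from, day_to)) |>
    dplyr::group_by(.data$treatment, .data$day, .data$nutrient) |>
    dplyr::summarise(conc = mean(.data$conc_used),
                     censored = any(.data$below_detection),
                     .groups = "drop")
  draw <- nut |>
    tidyr::pivot_wider(names_from = "day", values_from = c("conc", "censored"),
                       names_sep = "_d") |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      drawdown_nmol_l = sum(.data[[paste0("conc_d", day_from)]] -
                              .data[[paste0("conc_d", day_to)]]),
      endpoint_censored = any(.data[[paste0("censored_d", day_to)]]),
      .groups = "drop")

  bio <- dplyr::as_tibble(biomass) |>
    dplyr::filter(.data$day %in% c(day_from, day_to)) |>
    dplyr::group_by(.data$treatment, .data$day, .data$group) |>
    dplyr::summarise(n = mean(.data$n_nmol_l), .groups = "drop")
  inc <- bio |>
    tidyr::pivot_wider(names_from = "day", values_from = "n",
                       names_prefix = "d") |>
    dplyr::mutate(increment = .data[[paste0("d", day_to)]] -
                    .data[[paste0("d", day_from)]])
  tot_inc <- inc |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(biomass_increment_nmol_l = sum(.data$increment),
                     .groups = "drop")

  out <- dplyr::left_join(draw, tot_inc, by = "treatment") |>
    dplyr::mutate(ratio = ifelse(.data$drawdown_nmol_l == 0 &
                                   .data$biomass_increment_nmol_l == 0,
                                 NA_real_,
                                 .data$biomass_increment_nmol_l /
                                   .data$drawdown_nmol_l))

  if (!is.null(arr)) {
    span <- day_to - day_from
    fix <- dplyr::as_tibble(arr) |>
      dplyr::group_by(.data$treatment) |>
      dplyr::summarise(
        fixation_n_nmol_l =
          mean(ethylene_to_fixed_n(.data$ethylene_nmol_l_d)) * span,
        .groups = "drop")
    # trapezoidal mortality-loss integral over the Cro biomass series
    cro_series <- dplyr::as_tibble(biomass) |>
      dplyr::filter(.data$group == "Cro") |>
      dplyr::group_by(.data$treatment, .data$day) |>
      dplyr::summarise(n = mean(.data$n_nmol_l), .groups = "drop") |>
      dplyr::filter(.data$day >= day_from, .data$day <= day_to) |>
      dplyr::arrange(.data$treatment, .data$day) |>
      dplyr::group_by(.data$treatment) |>
      dplyr::summarise(
        mort_loss = cro_mortality * sum(diff(.data$day) *
                                          (utils::head(.data$n, -1) +
                                             utils::tail(.data$n, -1)) / 2),
        .groups = "drop")
    cro_inc <- inc |>
      dplyr::filter(.data$group == "Cro") |>
      dplyr::select("treatment", cro_increment = "increment")
    out <- out |>
      dplyr::left_join(fix, by = "treatment") |>
      dplyr::left_join(cro_series, by = "treatment") |>
      dplyr::left_join(cro_inc, by = "treatment") |>
      dplyr::mutate(
        cro_demand_nmol_l = .data$cro_increment +
          if (demand == "gross") .data$mort_loss else 0,
        pct_fixation = fixation_fraction_of_demand(
          .data$cro_increment,
          if (demand == "gross") .data$mort_loss else 0,
          .data$fixation_n_nmol_l)) |>
      dplyr::select(-"mort_loss", -"cro_increment")
  }
  structure(out, class = c("croco_budget", class(tibble::tibble())))
}

#' @method autoplot croco_budget
#' @export
autoplot.croco_budget <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              cols = c("drawdown_nmol_l",
                                       "biomass_increment_nmol_l"),
                              names_to = "quantity", values_to = "nmol_l")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$treatment, y = .data$nmol_l,
                                     fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "nmol N L⁻¹", fill = NULL) +
    ggplot2::theme_minimal()
}
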