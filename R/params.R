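#' Phytoplankton group parameters
#'
#' Bundles the kinetic and loss constants of one phytoplankton group for the
#' sum-of-Monod growth model: maximum specific uptake rates for ammonium and
#' nitrate, the corresponding half-saturation constants, a linear mortality
#' rate, and an optional diazotrophy growth-rate floor. Units are fixed
#' package-wide: pools and nutrient concentrations in nmol N L^-1, rates in
#' d^-1, time in days.
#'
#' @param name Group label, e.g. `"Cro"` (Crocosphaera) or `"Oth"` (other
#'   phytoplankton).
#' @param vmax_nh4,vmax_no3 Maximum specific uptake rates for NH4+ and NO3-,
#'   in mol N (mol cell N)^-1 d^-1, i.e. d^-1. Must be >= 0.
#' @param k_nh4,k_no3 Half-saturation constants for NH4+ and NO3- uptake,
#'   nmol L^-1. Must be > 0.
#' @param mortality Linear mortality rate, d^-1. Must be >= 0.
#' @param diazotroph_floor Optional floor growth rate sustained by N2
#'   fixation, d^-1 (`NULL` for non-diazotrophs). When supplied it must not
#'   exceed `vmax_nh4 + vmax_no3`.
#'
#' @return An object of class `phyto_params` (a named list).
#' @seealso [default_phyto_params()], [monod_growth_rate()]
#' @examples
#' cro <- phyto_params("Cro", vmax_nh4 = 6.6, vmax_no3 = 2, k_nh4 = 200,
#'                     k_no3 = 50, mortality = 0.1, diazotroph_floor = 0.31)
#' monod_growth_rate(cro, nutrient_pair(100, 100))
#' @export
phyto_params <- function(name, vmax_nh4, vmax_no3, k_nh4, k_no3,
                         mortality = 0, diazotroph_floor = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(x, what, strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(what, " must be a single finite number", call. = FALSE)
    if (x < 0 || (strict && x == 0))
      stop(what, if (strict) " must be > 0" else " must be >= 0", call. = FALSE)
    as.numeric(x)
  }
  vmax_nh4 <- num1(vmax_nh4, "vmax_nh4")
  vmax_no3 <- num1(vmax_no3, "vmax_no3")
  k_nh4 <- num1(k_nh4, "k_nh4", strict = TRUE)
  k_no3 <- num1(k_no3, "k_no3", strict = TRUE)
  mortality <- num1(mortality, "mortality")
  if (!is.null(diazotroph_floor)) {
    diazotroph_floor <- num1(diazotroph_floor, "diazotroph_floor")
    if (diazotroph_floor > vmax_nh4 + vmax_no3)
      stop("diazotroph_floor must not exceed vmax_nh4 + vmax_no3",
           call. = FALSE)
  }
  structure(
    list(name = name, vmax_nh4 = vmax_nh4, vmax_no3 = vmax_no3,
         k_nh4 = k_nh4, k_no3 = k_no3, mortality = mortality,
         diazotroph_floor = diazotroph_floor),
    class = "phyto_params"
  )
}

#' @export
print.phyto_params <- function(x, ...) {
  cat("<phyto_params> ", x$name, "\n", sep = "")
  cat(sprintf("  Vmax NH4 %.3g, Vmax NO3 %.3g d^-1 | K NH4 %.3g, K NO3 %.3g nmol/L\n",
              x$vmax_nh4, x$vmax_no3, x$k_nh4, x$k_no3))
  cat(sprintf("  mortality %.3g d^-1", x$mortality))
  if (!is.null(x$diazotroph_floor))
    cat(sprintf(" | diazotrophy floor %.3g d^-1", x$diazotroph_floor))
  cat("\n")
  invisible(x)
}

#' Zooplankton grazing parameters
#'
#' Parameters of the kill-the-winner grazer: maximum grazing rate, grazing
#' half-saturation (on total prey N), and a quadratic mortality coefficient.
#'
#' @param g_max Maximum grazing rate, d^-1 (>= 0).
#' @param k_g Grazing half-saturation on total prey N, nmol L^-1 (> 0).
#' @param m_zoo Quadratic mortality coefficient, (nmol L^-1)^-1 d^-1 (>= 0).
#'
#' @return An object of class `zoo_params`.
#' @export
zoo_params <- function(g_max = 1.0, k_g = 5, m_zoo = 0.1) {
  stopifnot(is.numeric(g_max), g_max >= 0, is.finite(g_max),
            is.numeric(k_g), k_g > 0, is.finite(k_g),
            is.numeric(m_zoo), m_zoo >= 0, is.finite(m_zoo))
  structure(list(g_max = as.numeric(g_max), k_g = as.numeric(k_g),
                 m_zoo = as.numeric(m_zoo)),
            class = "zoo_params")
}

#' @export
print.zoo_params <- function(x, ...) {
  cat(sprintf("<zoo_params> Gmax %.3g d^-1, K_G %.3g nmol/L, m_zoo %.3g (nmol/L)^-1 d^-1\n",
              x$g_max, x$k_g, x$m_zoo))
  invisible(x)
}

#' Ambient nutrient pair
#'
#' A pair of combined-nitrogen concentrations (ammonium, nitrate) in
#' nmol L^-1. Negative concentrations are rejected here; clipping of
#' negative *model-evaluated* forcings is the forcing module's job.
#'
#' @param nh4,no3 Concentrations, nmol L^-1 (>= 0).
#' @return An object of class `nutrient_pair`.
#' @export
nutrient_pair <- function(nh4, no3) {
  if (!is.numeric(nh4) || !is.numeric(no3) || anyNA(nh4) || anyNA(no3))
    stop("nutrient concentrations must be numeric and non-missing", call. = FALSE)
  if (any(nh4 < 0) || any(no3 < 0))
    stop("negative nutrient concentration", call. = FALSE)
  structure(list(nh4 = as.numeric(nh4), no3 = as.numeric(no3)),
            class = "nutrient_pair")
}

#' Ecosystem state (cellular N pools)
#'
#' @param n_cro,n_oth,n_zoo Cellular nitrogen pools of Crocosphaera, other
#'   phytoplankton and zooplankton, nmol N L^-1 (>= 0).
#' @return An object of class `ecosystem_state`.
#' @export
ecosystem_state <- function(n_cro, n_oth, n_zoo) {
  v <- c(n_cro = n_cro, n_oth = n_oth, n_zoo = n_zoo)
  if (!is.numeric(v) || anyNA(v) || any(v < 0))
    stop("ecosystem pools must be non-negative numbers", call. = FALSE)
  structure(as.list(as.numeric(v)) |> stats::setNames(c("n_cro", "n_oth", "n_zoo")),
            class = "ecosystem_state")
}

#' Default phytoplankton parameter sets
#'
#' Two-group defaults for the incubation and ecosystem models. The NH4+
#' maximum uptake rates (6.6 d^-1 for Crocosphaera, 1.1 d^-1 for other
#' phytoplankton) are the published values; the remaining constants
#' (NO3- Vmax, half-saturations, mortality) are package defaults chosen to
#' respect the qualitative pattern of the system — Crocosphaera has the
#' higher NO3- uptake capacity but a relatively high NH4+ half-saturation,
#' so it is competitive when nutrients are replete and handicapped when they
#' are scarce. Override any of them via [phyto_params()] or a YAML config.
#'
#' @param fixation Logical; if `TRUE` the Crocosphaera set carries the
#'   0.31 d^-1 diazotrophy floor, otherwise no floor.
#' @return A named list with elements `cro` and `oth`, each `phyto_params`.
#' @export
default_phyto_params <- function(fixation = TRUE) {
  list(
    cro = phyto_params("Cro", vmax_nh4 = 6.6, vmax_no3 = 2.0,
                       k_nh4 = 200, k_no3 = 50, mortality = 0.1,
                       diazotroph_floor = if (fixation) 0.31 else NULL),
    oth = phyto_params("Oth", vmax_nh4 = 1.1, vmax_no3 = 0.8,
                       k_nh4 = 20, k_no3 = 20, mortality = 0.1)
  )
}

#' Read/write model parameters as YAML
#'
#' The config schema mirrors the parameter objects:
#' `groups.<name>.{vmax_nh4, vmax_no3, k_nh4, k_no3, mortality,
#' diazotroph_floor}` and `zoo.{g_max, k_g, m_zoo}`.
#'
#' @param path Path to a YAML file.
#' @return `read_params_config()` returns `list(groups = <named list of
#'   phyto_params>, zoo = <zoo_params or NULL>)`.
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups) || !length(cfg$groups))
    stop("config has no 'groups' block", call. = FALSE)
  groups <- purrr::imap(cfg$groups, function(g, nm) {
    phyto_params(nm,
                 vmax_nh4 = g$vmax_nh4, vmax_no3 = g$vmax_no3,
                 k_nh4 = g$k_nh4, k_no3 = g$k_no3,
                 mortality = g$mortality %||% 0,
                 diazotroph_floor = g$diazotroph_floor)
  })
  zoo <- if (!is.null(cfg$zoo))
    zoo_params(cfg$zoo$g_max, cfg$zoo$k_g, cfg$zoo$m_zoo)
  list(groups = groups, zoo = zoo)
}

#' @rdname read_params_config
#' @param groups Named list of `phyto_params`.
#' @param zoo Optional `zoo_params`.
#' @export
write_params_config <- function(groups, zoo = NULL, path) {
  cfg <- list(groups = purrr::map(groups, function(g) {
    out <- g[c("vmax_nh4", "vmax_no3", "k_nh4", "k_no3", "mortality")]
    if (!is.null(g$diazotroph_floor)) out$diazotroph_floor <- g$diazotroph_floor
    out
  }))
  if (!is.null(zoo)) cfg$zoo <- unclass(zoo)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
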