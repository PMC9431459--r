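#' Sum-of-Monod specific growth rate
#'
#' The specific growth rate of a phytoplankton group is the sum of two
#' Monod (saturating hyperbolic) terms, one per combined-nitrogen source:
#'
#' \deqn{\mu = V^{NH4}_{max}\frac{[NH_4^+]}{[NH_4^+]+K^{NH4}} +
#'       V^{NO3}_{max}\frac{[NO_3^-]}{[NO_3^-]+K^{NO3}}}
#'
#' The result is bounded in `[0, vmax_nh4 + vmax_no3]`, continuous, and
#' monotone nondecreasing in each nutrient.
#'
#' @param params A [phyto_params()] object.
#' @param nutrients A [nutrient_pair()] (elements may be vectors of equal
#'   length, in which case a vector of rates is returned).
#' @return Specific growth rate(s), d^-1.
#' @export
monod_growth_rate <- function(params, nutrients) {
  stopifnot(inherits(params, "phyto_params"), inherits(nutrients, "nutrient_pair"))
  params$vmax_nh4 * nutrients$nh4 / (nutrients$nh4 + params$k_nh4) +
    params$vmax_no3 * nutrients$no3 / (nutrients$no3 + params$k_no3)
}

#' Realized growth rate with optional diazotrophy floor
#'
#' When N2 fixation is enabled for a diazotroph, the realized growth rate is
#' the Monod uptake rate or the diazotrophy floor (0.31 d^-1 for
#' Crocosphaera, a typical growth rate under diazotrophic conditions),
#' whichever is larger: fixation keeps the cell growing when combined N is
#' depleted, but confers no advantage once uptake exceeds the floor.
#'
#' @inheritParams monod_growth_rate
#' @param fixation_enabled Logical; apply the floor? Requires `params` to
#'   carry a `diazotroph_floor`.
#' @return Realized specific growth rate(s), d^-1.
#' @export
effective_growth_rate <- function(params, nutrients, fixation_enabled = FALSE) {
  mu <- monod_growth_rate(params, nutrients)
  if (!fixation_enabled) return(mu)
  if (is.null(params$diazotroph_floor))
    stop("fixation_enabled = TRUE but group '", params$name,
         "' has no diazotroph_floor", call. = FALSE)
  pmax(mu, params$diazotroph_floor)
}

#' Kill-the-winner grazing rates
#'
#' Per-prey grazing rates under active prey switching: pressure on each prey
#' is weighted by its squared share of total prey N, scaled by a saturating
#' (Holling type III style) response in total prey:
#'
#' \deqn{G_i = G_{max}\,\frac{N_i^2}{N_{Cro}^2+N_{Oth}^2}\;
#'       \frac{(N_{Cro}+N_{Oth})^2}{(N_{Cro}+N_{Oth})^2+K_G^2}}
#'
#' Consequences tested as invariants: the rates sum to
#' `g_max * N_tot^2 / (N_tot^2 + k_g^2)` and their ratio is
#' `(n_cro/n_oth)^2` whenever both prey are positive — the more abundant
#' prey is grazed disproportionately, which stabilises coexistence. With no
#' prey at all the rates are 0 by definition (no prey, no grazing), which
#' removes the 0/0 singularity.
#'
#' @param state An [ecosystem_state()].
#' @param zoo A [zoo_params()].
#' @return Named numeric vector `c(g_cro = , g_oth = )`, d^-1.
#' @export
ktw_grazing_rates <- function(state, zoo) {
  stopifnot(inherits(state, "ecosystem_state"), inherits(zoo, "zoo_params"))
  .ktw(state$n_cro, state$n_oth, zoo$g_max, zoo$k_g)
}

# internal, unclassed hot path shared with the integrator
.ktw <- function(n_cro, n_oth, g_max, k_g) {
  tot <- n_cro + n_oth
  if (tot <= 0) return(c(g_cro = 0, g_oth = 0))
  sq <- n_cro^2 + n_oth^2
  # k_g = 0 degenerates to saturation 1, allowed
  sat <- if (k_g > 0) tot^2 / (tot^2 + k_g^2) else 1
  c(g_cro = g_max * (n_cro^2 / sq) * sat,
    g_oth = g_max * (n_oth^2 / sq) * sat)
}

#' Incubation growth derivative for one group
#'
#' `dN/dt = (mu - m) N` with `mu` from [monod_growth_rate()]: net balance of
#' nutrient-limited growth and linear mortality, no grazing (the bottle
#' incubations exclude larger grazers).
#'
#' @param state_n Cellular N pool, nmol L^-1 (>= 0).
#' @inheritParams monod_growth_rate
#' @return dN/dt, nmol L^-1 d^-1.
#' @export
incubation_derivative <- function(state_n, params, nutrients) {
  if (!is.numeric(state_n) || anyNA(state_n) || any(state_n < 0))
    stop("state_n must be non-negative", call. = FALSE)
  (monod_growth_rate(params, nutrients) - params$mortality) * state_n
}

#' Ecosystem derivatives (phytoplankton + KTW grazer)
#'
#' The three-pool competition model: two phytoplankton groups grow on shared
#' nutrients and are grazed by one zooplankton pool with kill-the-winner
#' switching; zooplankton suffer quadratic mortality:
#'
#' \deqn{dN_i/dt = \mu_i N_i - G_i N_{Zoo}}
#' \deqn{dN_{Zoo}/dt = (G_{Cro}+G_{Oth}) N_{Zoo} - m_{Zoo} N_{Zoo}^2}
#'
#' Nitrogen grazed off the phytoplankton appears one-for-one in the
#' zooplankton pool, so
#' `d(total N)/dt = mu_cro*N_cro + mu_oth*N_oth - m_zoo*N_zoo^2` exactly.
#'
#' @param state An [ecosystem_state()].
#' @param cro,oth [phyto_params()] for the two groups.
#' @param zoo A [zoo_params()].
#' @param nutrients A [nutrient_pair()].
#' @param fixation_enabled Logical; apply the Crocosphaera diazotrophy floor.
#' @return Named numeric vector `c(n_cro = , n_oth = , n_zoo = )`,
#'   nmol L^-1 d^-1.
#' @export
ecosystem_derivatives <- function(state, cro, oth, zoo, nutrients,
                                  fixation_enabled = FALSE) {
  stopifnot(inherits(state, "ecosystem_state"))
  mu_cro <- effective_growth_rate(cro, nutrients, fixation_enabled)
  mu_oth <- monod_growth_rate(oth, nutrients)
  g <- .ktw(state$n_cro, state$n_oth, zoo$g_max, zoo$k_g)
  c(n_cro = mu_cro * state$n_cro - g[["g_cro"]] * state$n_zoo,
    n_oth = mu_oth * state$n_oth - g[["g_oth"]] * state$n_zoo,
    n_zoo = (g[["g_cro"]] + g[["g_oth"]]) * state$n_zoo -
      zoo$m_zoo * state$n_zoo^2)
}
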