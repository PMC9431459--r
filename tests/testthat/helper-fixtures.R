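# shared fixtures: small parameter sets and forcings used across test files

cro_pars <- function(floor = 0.31) {
  phyto_params("Cro", vmax_nh4 = 6.6, vmax_no3 = 2.0, k_nh4 = 200,
               k_no3 = 50, mortality = 0.1, diazotroph_floor = floor)
}

oth_pars <- function() {
  phyto_params("Oth", vmax_nh4 = 1.1, vmax_no3 = 0.8, k_nh4 = 20,
               k_no3 = 20, mortality = 0.1)
}

# drawdown-shaped quadratic NH4 forcing (105 -> ~5 nmol/L over 3 d) with
# constant NO3, the shape of an N-amended incubation
m3_forcing <- function() {
  nutrient_forcing(nh4 = c(10, -63, 105), no3 = 15)
}

# random positive ecosystem states for property tests
random_states <- function(n, seed = 1, max_n = 50) {
  set.seed(seed)
  tibble::tibble(
    n_cro = runif(n, 1e-3, max_n),
    n_oth = runif(n, 1e-3, max_n),
    n_zoo = runif(n, 1e-3, max_n / 5)
  )
}
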