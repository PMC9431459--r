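# size calibration -----------------------------------------------------------

test_that("exact power-law beads give back the power-law exponent", {
  d <- c(1.75, 2, 3, 6, 10)
  beads <- tibble::tibble(diameter_um = d, fls = 50 * d^2.5)
  cal <- calibrate_size(beads)
  expect_equal(cal$slope, 1 / 2.5, tolerance = 1e-12)
  expect_equal(exp(cal$intercept + cal$slope * log(beads$fls)), d,
               tolerance = 1e-12)
})

test_that("two standards define the line exactly; one diameter fails", {
  beads <- tibble::tibble(diameter_um = c(2, 6), fls = c(90, 1400))
  cal <- calibrate_size(beads)
  expect_equal(exp(cal$intercept + cal$slope * log(c(90, 1400))), c(2, 6),
               tolerance = 1e-12)
  expect_error(calibrate_size(tibble::tibble(diameter_um = c(2, 2),
                                             fls = c(90, 95))),
               "distinct")
})

test_that("noisy bead calibration matches closed-form OLS and stays within 5%", {
  set.seed(7)
  d <- c(1.75, 2, 3, 6, 10)
  fls <- 50 * d^2.5 * exp(rnorm(5, 0, 0.02))
  cal <- calibrate_size(tibble::tibble(diameter_um = d, fls = fls))
  # independent oracle: normal equations on the log-log design
  X <- cbind(1, log(fls))
  beta <- solve(t(X) %*% X, t(X) %*% log(d))
  expect_equal(c(cal$intercept, cal$slope), as.vector(beta), tolerance = 1e-10)
  fitted_d <- exp(cal$intercept + cal$slope * log(fls))
  expect_true(all(abs(fitted_d - d) / d < 0.05))
})

# volume and carbon -----------------------------------------------------------

test_that("FLS converts to spherical volume, with flagged extrapolation", {
  d <- c(1.75, 2, 3, 6, 10)
  cal <- calibrate_size(tibble::tibble(diameter_um = d, fls = 50 * d^2.5))
  v6 <- fls_to_volume(cal, 50 * 6^2.5)
  expect_equal(v6, pi / 6 * 216, tolerance = 1e-9)
  # cubic scaling: d = 2 has 8x the volume of d = 1 (both extrapolated cases ok)
  suppressWarnings({
    v1 <- fls_to_volume(cal, 50 * 1^2.5)
    v2 <- fls_to_volume(cal, 50 * 2^2.5)
  })
  expect_equal(v1, pi / 6, tolerance = 1e-9)
  expect_equal(v2 / v1, 8, tolerance = 1e-9)
  expect_warning(fls_to_volume(cal, 1), "extrapolat")
  expect_error(fls_to_volume(cal, 0), "> 0")
})

test_that("carbon models hit their printed anchors and scaling laws", {
  conv <- default_conversions()
  # cyanobacterial density: 235 fg C per um^3
  expect_equal(carbon_per_cell(conv$Cro, 1), 235)
  expect_equal(carbon_per_cell(conv$Cro, 2), 470)  # linear in volume
  # Strathmann at V = 1 um^3: 10^-0.6 pg = 251.19 fg
  expect_equal(carbon_per_cell(conv$PicoE, 1), 1000 * 10^(-0.6),
               tolerance = 1e-9)
  # Strathmann is a power law with exponent 0.94 on the log-log scale
  v <- c(0.5, 1, 2, 5, 20)
  slope <- coef(lm(log10(carbon_per_cell(conv$PicoE, v)) ~ log10(v)))[2]
  expect_equal(unname(slope), 0.94, tolerance = 1e-10)
  expect_error(carbon_per_cell(conv$Cro, 0), "> 0")
})

test_that("C:N conversion: 8.7 fmol C per fmol N for Crocosphaera", {
  conv <- default_conversions()
  # carbon worth 8.7 fmol C (in fg) maps to exactly 1 fmol N
  expect_equal(nitrogen_per_cell(conv$Cro, 8.7 * 12.011), 1)
  expect_equal(nitrogen_per_cell(conv$PicoE, 6.6 * 12.011), 1)
  expect_equal(nitrogen_per_cell(conv$Cro, 0), 0)
})

# population biomass ----------------------------------------------------------

test_that("population biomass applies the unit chain correctly", {
  d <- c(1.75, 2, 3, 6, 10)
  cal <- calibrate_size(tibble::tibble(diameter_um = d, fls = 50 * d^2.5))
  fcm <- tibble::tibble(day = 0, treatment = "control", replicate = 1,
                        group = "Cro", abundance_cells_per_ml = 1000,
                        median_fls = 50 * 3^2.5)
  out <- estimate_biomass(fcm, cal)
  # dimensional-analysis oracle: per-cell N in fmol, x cells/L, / 1e6 -> nmol/L
  vol <- pi / 6 * 27
  n_cell <- (235 * vol / 12.011) / 8.7           # fmol N per cell
  expect_equal(out$n_nmol_l, 1000 * 1000 * n_cell / 1e6, tolerance = 1e-9)
  expect_equal(out$c_nmol_l, 1000 * 1000 * (235 * vol / 12.011) / 1e6,
               tolerance = 1e-9)
  # linearity in abundance; zero abundance, zero biomass
  out2 <- estimate_biomass(dplyr::mutate(fcm, abundance_cells_per_ml = 2000), cal)
  expect_equal(out2$n_nmol_l, 2 * out$n_nmol_l)
  out0 <- estimate_biomass(dplyr::mutate(fcm, abundance_cells_per_ml = 0), cal)
  expect_equal(out0$n_nmol_l, 0)
  # unknown group is rejected
  expect_error(estimate_biomass(dplyr::mutate(fcm, group = "Mystery"), cal),
               "Mystery")
})

test_that("unit conversion table: fg-fmol at 12.011, mL-L, fmol-nmol", {
  # one table of dimensional anchors, checked once
  expect_equal(12.011 / 12.011, 1)                       # fg C == 1/12.011 fmol
  expect_equal(nitrogen_per_cell(group_conversion("x", "volumetric",
                                                  factor = 1, cn_ratio = 1),
                                 12.011), 1)             # fg -> fmol at C/N 1
  # 1e6 cells/L at 1 fmol N/cell = 1e6 fmol/L = 1 nmol/L
  expect_equal(1e6 * 1 / 1e6, 1)
})

# fixation ---------------------------------------------------------------------

test_that("acetylene reduction converts 4:1 to N2 and 2:1 to N atoms", {
  expect_equal(ethylene_to_fixed_n(4, as = "n2"), 1)
  expect_equal(ethylene_to_fixed_n(4, as = "n_atoms"), 2)
  expect_equal(ethylene_to_fixed_n(0), 0)
  # linearity
  expect_equal(ethylene_to_fixed_n(3) + ethylene_to_fixed_n(5),
               ethylene_to_fixed_n(8))
  expect_error(ethylene_to_fixed_n(-1), ">= 0")
})

test_that("fixation share of demand follows its definition", {
  expect_equal(fixation_fraction_of_demand(10, 0, 10), 100)
  expect_equal(fixation_fraction_of_demand(10, 0, 0), 0)
  # known increments: delta 9, mortality loss 1, fixation 1 -> 10%
  expect_equal(fixation_fraction_of_demand(9, 1, 1), 10)
  expect_warning(out <- fixation_fraction_of_demand(-2, 1, 1), "undefined")
  expect_true(is.na(out))
  expect_warning(fixation_fraction_of_demand(1, 0, 2), "100")
})

# budget -------------------------------------------------------------------------

test_that("drawdown vs biomass budget recovers constructed ratios", {
  nutrients <- tidyr::crossing(day = c(0, 3), treatment = "t1", replicate = 1:3,
                               nutrient = c("nh4", "no3")) |>
    dplyr::mutate(conc_nmol_l = ifelse(day == 0, 50, 30),
                  below_detection = FALSE)
  # drawdown 2 x 20 = 40; constructed increment 20 -> ratio 0.5
  biomass <- tidyr::crossing(day = c(0, 3), treatment = "t1", replicate = 1:3,
                             group = c("Cro", "Oth")) |>
    dplyr::mutate(n_nmol_l = ifelse(day == 0, 10, 20))
  b <- nitrogen_budget(nutrients, biomass)
  expect_equal(b$drawdown_nmol_l, 40)
  expect_equal(b$biomass_increment_nmol_l, 20)
  expect_equal(b$ratio, 0.5)
  expect_false(b$endpoint_censored)

  # increment equal to drawdown -> ratio 1
  biomass2 <- dplyr::mutate(biomass, n_nmol_l = ifelse(day == 0, 10, 30))
  expect_equal(nitrogen_budget(nutrients, biomass2)$ratio, 1)

  # zero drawdown with zero increment -> flagged NA, not NaN chaos
  nut0 <- dplyr::mutate(nutrients, conc_nmol_l = 50)
  bio0 <- dplyr::mutate(biomass, n_nmol_l = 10)
  expect_true(is.na(nitrogen_budget(nut0, bio0)$ratio))
})

test_that("budget ratio is invariant under uniform rescaling", {
  nutrients <- tidyr::crossing(day = c(0, 3), treatment = "t1", replicate = 1:3,
                               nutrient = c("nh4", "no3")) |>
    dplyr::mutate(conc_nmol_l = ifelse(day == 0, 80, 35),
                  below_detection = FALSE)
  biomass <- tidyr::crossing(day = c(0, 3), treatment = "t1", replicate = 1:3,
                             group = c("Cro", "Oth")) |>
    dplyr::mutate(n_nmol_l = ifelse(day == 0, 12, 31))
  r1 <- nitrogen_budget(nutrients, biomass)$ratio
  k <- 3.7
  r2 <- nitrogen_budget(dplyr::mutate(nutrients, conc_nmol_l = k * conc_nmol_l),
                        dplyr::mutate(biomass, n_nmol_l = k * n_nmol_l))$ratio
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("budget flags censored endpoints and rejects mismatched tables", {
  nutrients <- tidyr::crossing(day = c(0, 3), treatment = "t1", replicate = 1,
                               nutrient = c("nh4", "no3")) |>
    dplyr::mutate(conc_nmol_l = ifelse(day == 0, 50, 2),
                  below_detection = day == 3)
  biomass <- tidyr::crossing(day = c(0, 3), treatment = "t1", replicate = 1,
                             group = "Cro") |>
    dplyr::mutate(n_nmol_l = ifelse(day == 0, 10, 40))
  b <- nitrogen_budget(nutrients, biomass)
  expect_true(b$endpoint_censored)
  # censored endpoint replaced by half the detection limit before differencing
  expect_equal(b$drawdown_nmol_l, (50 - 3) + (50 - 1.5))
  expect_error(nitrogen_budget(nutrients,
                               dplyr::mutate(biomass, treatment = "other")),
               "different treatments")
})
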