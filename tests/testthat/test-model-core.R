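# growth kinetics ----------------------------------------------------------

test_that("sum-of-Monod growth rate matches its closed-form anchors", {
  cro <- cro_pars()
  # no substrate, no growth
  expect_identical(monod_growth_rate(cro, nutrient_pair(0, 0)), 0)
  # saturating NH4 alone approaches the published 6.6 d^-1 maximum
  expect_equal(monod_growth_rate(cro, nutrient_pair(1e6 * cro$k_nh4, 0)),
               6.6, tolerance = 1e-5)
  # half-saturation definition
  expect_equal(monod_growth_rate(cro, nutrient_pair(cro$k_nh4, 0)),
               cro$vmax_nh4 / 2)
  # both nutrients saturating: bounded by the sum of maxima
  expect_equal(monod_growth_rate(cro, nutrient_pair(1e9, 1e9)),
               cro$vmax_nh4 + cro$vmax_no3, tolerance = 1e-5)
  expect_error(monod_growth_rate(cro, nutrient_pair(-1, 0)), "negative")
})

test_that("growth rate is monotone nondecreasing in each nutrient", {
  set.seed(11)
  for (i in 1:50) {
    p <- phyto_params("g", vmax_nh4 = runif(1, 0, 10), vmax_no3 = runif(1, 0, 10),
                      k_nh4 = runif(1, 1, 500), k_no3 = runif(1, 1, 500))
    nh4 <- sort(runif(2, 0, 1000)); no3 <- sort(runif(2, 0, 1000))
    expect_gte(monod_growth_rate(p, nutrient_pair(nh4[2], no3[1])),
               monod_growth_rate(p, nutrient_pair(nh4[1], no3[1])))
    expect_gte(monod_growth_rate(p, nutrient_pair(nh4[1], no3[2])),
               monod_growth_rate(p, nutrient_pair(nh4[1], no3[1])))
    mu <- monod_growth_rate(p, nutrient_pair(nh4[2], no3[2]))
    expect_gte(mu, 0)
    expect_lte(mu, p$vmax_nh4 + p$vmax_no3)
  }
})

test_that("diazotrophy floor engages only below 0.31 d^-1", {
  cro <- cro_pars()
  # starved diazotroph falls back on fixation
  expect_equal(effective_growth_rate(cro, nutrient_pair(0, 0), TRUE), 0.31)
  # saturating NH4: uptake dwarfs the floor
  expect_equal(effective_growth_rate(cro, nutrient_pair(1e9, 0), TRUE),
               6.6, tolerance = 1e-5)
  # flag off: plain Monod
  expect_equal(effective_growth_rate(cro, nutrient_pair(0, 0), FALSE), 0)
  # non-diazotroph starves regardless of the flag being off
  expect_equal(effective_growth_rate(oth_pars(), nutrient_pair(0, 0), FALSE), 0)
  # flag on for a group without a floor is a configuration error
  expect_error(effective_growth_rate(oth_pars(), nutrient_pair(0, 0), TRUE),
               "diazotroph_floor")
})

# kill-the-winner grazing ---------------------------------------------------

test_that("KTW grazing matches a term-by-term independent evaluation", {
  zoo <- zoo_params(g_max = 1.3, k_g = 7, m_zoo = 0.05)
  st <- random_states(200, seed = 21)
  for (i in seq_len(nrow(st))) {
    s <- ecosystem_state(st$n_cro[i], st$n_oth[i], st$n_zoo[i])
    g <- ktw_grazing_rates(s, zoo)
    # independent brute-force evaluation of the switching formula
    tot <- st$n_cro[i] + st$n_oth[i]
    sat <- tot^2 / (tot^2 + zoo$k_g^2)
    pref_cro <- st$n_cro[i]^2 / (st$n_cro[i]^2 + st$n_oth[i]^2)
    expect_equal(unname(g["g_cro"]), zoo$g_max * pref_cro * sat)
    expect_equal(unname(g["g_oth"]), zoo$g_max * (1 - pref_cro) * sat)
    # sum identity and squared prey-switching ratio
    expect_equal(sum(g), zoo$g_max * sat, tolerance = 1e-12)
    expect_equal(unname(g["g_cro"] / g["g_oth"]),
                 (st$n_cro[i] / st$n_oth[i])^2, tolerance = 1e-9)
  }
})

test_that("KTW degenerate cases: equal prey, single prey, no prey, k_g = 0", {
  zoo <- zoo_params(g_max = 2, k_g = 5)
  g_eq <- ktw_grazing_rates(ecosystem_state(3, 3, 1), zoo)
  sat <- 36 / (36 + 25)
  expect_equal(unname(g_eq["g_cro"]), zoo$g_max / 2 * sat)
  expect_equal(unname(g_eq["g_cro"]), unname(g_eq["g_oth"]))

  g_one <- ktw_grazing_rates(ecosystem_state(4, 0, 1), zoo)
  expect_equal(unname(g_one["g_oth"]), 0)
  expect_equal(unname(g_one["g_cro"]), zoo$g_max * 16 / (16 + 25))

  expect_equal(unname(ktw_grazing_rates(ecosystem_state(0, 0, 1), zoo)),
               c(0, 0))
  # k_g = 0: saturation term degenerates to 1
  g0 <- ktw_grazing_rates(ecosystem_state(1, 1, 1), zoo_params(g_max = 2, k_g = 1e-300))
  expect_equal(sum(g0), 2, tolerance = 1e-6)
})

# derivatives ---------------------------------------------------------------

test_that("incubation derivative is growth minus mortality times N", {
  p <- phyto_params("g", vmax_nh4 = 1, vmax_no3 = 0, k_nh4 = 10, k_no3 = 10,
                    mortality = 0.1)
  # extinction is absorbing
  expect_equal(incubation_derivative(0, p, nutrient_pair(100, 0)), 0)
  # mu = 0.5 (half saturation), m = 0.1, N = 10 -> 4.0
  expect_equal(incubation_derivative(10, p, nutrient_pair(10, 0)), 4.0)
  # balance point mu = m: nh4 such that 1*c/(c+10) = 0.1 -> c = 10/9
  expect_equal(incubation_derivative(5, p, nutrient_pair(10 / 9, 0)), 0,
               tolerance = 1e-12)
  expect_error(incubation_derivative(-1, p, nutrient_pair(1, 1)),
               "non-negative")
})

test_that("ecosystem derivatives conserve grazed nitrogen exactly", {
  cro <- cro_pars(); oth <- oth_pars()
  zoo <- zoo_params(g_max = 1, k_g = 5, m_zoo = 0.1)
  nut <- nutrient_pair(20, 30)
  st <- random_states(100, seed = 31)
  for (i in seq_len(nrow(st))) {
    s <- ecosystem_state(st$n_cro[i], st$n_oth[i], st$n_zoo[i])
    d <- ecosystem_derivatives(s, cro, oth, zoo, nut, fixation_enabled = FALSE)
    mu_cro <- monod_growth_rate(cro, nut)
    mu_oth <- monod_growth_rate(oth, nut)
    # total-N budget: growth in, quadratic zoo mortality out, grazing cancels
    expect_equal(sum(d),
                 mu_cro * s$n_cro + mu_oth * s$n_oth - zoo$m_zoo * s$n_zoo^2,
                 tolerance = 1e-12)
  }
})

test_that("ecosystem derivatives: zero state and grazer-free reductions", {
  cro <- cro_pars(); oth <- oth_pars(); zoo <- zoo_params()
  nut <- nutrient_pair(10, 10)
  expect_equal(unname(ecosystem_derivatives(ecosystem_state(0, 0, 0),
                                            cro, oth, zoo, nut)),
               c(0, 0, 0))
  d <- ecosystem_derivatives(ecosystem_state(2, 3, 0), cro, oth, zoo, nut)
  expect_equal(unname(d["n_cro"]), monod_growth_rate(cro, nut) * 2)
  expect_equal(unname(d["n_oth"]), monod_growth_rate(oth, nut) * 3)
  expect_equal(unname(d["n_zoo"]), 0)
})

test_that("rate functions are pure (same inputs, same outputs)", {
  cro <- cro_pars(); nut <- nutrient_pair(37, 11)
  expect_identical(monod_growth_rate(cro, nut), monod_growth_rate(cro, nut))
  s <- ecosystem_state(2, 5, 1)
  expect_identical(ktw_grazing_rates(s, zoo_params()),
                   ktw_grazing_rates(s, zoo_params()))
})

test_that("parameter constructors enforce their invariants", {
  expect_error(phyto_params("x", vmax_nh4 = -1, vmax_no3 = 0, k_nh4 = 1, k_no3 = 1),
               ">= 0")
  expect_error(phyto_params("x", vmax_nh4 = 1, vmax_no3 = 0, k_nh4 = 0, k_no3 = 1),
               "> 0")
  expect_error(phyto_params("x", vmax_nh4 = 1, vmax_no3 = 1, k_nh4 = 1, k_no3 = 1,
                            diazotroph_floor = 3), "exceed")
  expect_error(zoo_params(k_g = 0))
  expect_error(nutrient_pair(-1, 0), "negative")
  expect_error(ecosystem_state(-1, 0, 0))
})
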