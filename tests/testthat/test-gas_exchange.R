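test_that("Schmidt polynomials match independent re-evaluation of the fits", {
  # independent oracle: raw polynomial evaluation written out separately
  sc_co2 <- function(T) 2116.8 - 136.25 * T + 4.7353 * T^2 - 0.09231 * T^3 +
    0.0007555 * T^4
  sc_ch4 <- function(T) 2101.2 - 131.54 * T + 4.4931 * T^2 - 0.08676 * T^3 +
    0.00070663 * T^4
  for (T in c(0, 5, 10, 21, 30, 40)) {
    expect_equal(schmidt_number("CO2", T), sc_co2(T), tolerance = 1e-9)
    expect_equal(schmidt_number("CH4", T), sc_ch4(T), tolerance = 1e-9)
  }
  expect_equal(schmidt_number("CO2", 0), 2116.8)
  expect_equal(schmidt_number("CO2", 21), 635.86, tolerance = 1e-4)
  expect_equal(schmidt_number("CH4", 21), 654.26, tolerance = 1e-4)
  expect_error(schmidt_number("CO2", 45), "fit range")
  expect_warning(schmidt_number("CO2", 45, out_of_range = "warn"), "fit range")
})

test_that("k600 registry evaluates the printed wind relations", {
  k6 <- function(m, u) switch(m, crusius_wanninkhof = 0.72 * u,
                              cole_caraco = 0.215 * u^1.7 + 2.07,
                              nightingale = 0.23 * u^2 + 0.1 * u)
  for (m in c("crusius_wanninkhof", "cole_caraco", "nightingale")) {
    for (u in c(0, 1, 2, 3.7, 8)) {
      expect_equal(k600_model(m, u), k6(m, u), tolerance = 1e-9)
    }
  }
  expect_equal(k600_model("cole_caraco", 0), 2.07)
  expect_equal(k600_model("crusius_wanninkhof", 2), 1.44)
  expect_equal(k600_model("cole_caraco", 2), 2.769, tolerance = 1e-3)
  expect_equal(k600_model("nightingale", 2), 1.12)
  expect_error(k600_model("wanninkhof92", 2), "valid models")
})

test_that("Schmidt scaling uses the wind-regime exponent", {
  expect_equal(transfer_velocity(5, 600, 1), 5)      # Sc = 600 normalisation
  expect_equal(transfer_velocity(5, 600, 8), 5)
  expect_equal(transfer_velocity(1.44, 654.26, 2),
               1.44 * (654.26 / 600)^-0.67, tolerance = 1e-12)
  expect_equal(transfer_velocity(1.44, 654.26, 2), 1.359, tolerance = 1e-3)
  expect_equal(transfer_velocity(1.44, 635.86, 2), 1.385, tolerance = 1e-3)
  # regime switch: exactly 3 m/s sits in the rough (-0.5) branch
  expect_equal(transfer_velocity(2, 900, 3), 2 * (1.5)^-0.5, tolerance = 1e-12)
  expect_equal(transfer_velocity(2, 900, 2.99), 2 * (1.5)^-0.67,
               tolerance = 1e-12)
})

test_that("equilibrium concentrations follow solubility times partial pressure", {
  expect_equal(equilibrium_concentration("CO2", 21, 0, 1), 0)
  p <- station_pressure(1884)
  expect_equal(p, exp(-1884 / 8400), tolerance = 1e-12)
  ceq_co2 <- equilibrium_concentration("CO2", 21, 410e-6, p)
  expect_equal(ceq_co2, 12.5, tolerance = 0.05)      # ~0.038 mol/L/atm x 328 uatm
  ceq_ch4 <- equilibrium_concentration("CH4", 21, 1.87e-6, p)
  expect_lt(ceq_ch4, 3e-3)                            # negligible vs C_w = 151
  expect_gt(ceq_ch4, 1e-3)
  # linear in mole fraction and pressure
  expect_equal(equilibrium_concentration("CO2", 21, 820e-6, p), 2 * ceq_co2,
               tolerance = 1e-12)
  expect_equal(equilibrium_concentration("CO2", 21, 410e-6, 2 * p), 2 * ceq_co2,
               tolerance = 1e-12)
})

test_that("chemical enhancement matches an independent evaluation on a grid", {
  for (tC in c(5, 15, 21, 30)) {
    cst <- carbonate_constants(tC)
    for (pH in c(7, 8.5, 9.5, 10.5)) {
      for (k in c(0.2, 1.385, 5, 50)) {
        b <- enhancement_factor(tC, pH, k, constants = cst)
        expect_equal(b$beta,
                     oracle_beta(tC, pH, k, cst$K1, cst$K2, cst$Kw,
                                 b$r1, b$r2),
                     tolerance = 1e-12)
        expect_gte(b$beta, 1)
      }
      # beta is non-increasing in k and -> 1 as k -> infinity
      ks <- c(0.1, 0.5, 2, 10, 100, 1e4, 1e6)
      betas <- vapply(ks, function(k)
        enhancement_factor(tC, pH, k, constants = cst)$beta, numeric(1))
      expect_true(all(diff(betas) <= 1e-12))
      expect_equal(betas[length(betas)], 1, tolerance = 1e-4)
    }
  }
})

test_that("enhancement intermediates match the printed diffusivity fit", {
  b <- enhancement_factor(21, 9.5, 1.385)
  expect_equal(b$D_cm2_s, 14.6836e-5 * (294.15 / 217.2056 - 1)^1.997,
               tolerance = 1e-12)
  expect_equal(b$D_cm2_s, 1.84e-5, tolerance = 5e-3)
  # hand-evaluated case with pinned rate constants and tau
  bb <- enhancement_factor(21, 9.5, 1.385,
                           constants = list(K1 = 4.2e-7, K2 = 4.3e-11,
                                            Kw = 7.4e-15),
                           r1 = 0.3 - 7.4e-15 / 10^-9.5 * 6209,  # force r = 0.3
                           r2 = 6209)
  expect_equal(bb$r, 0.3, tolerance = 1e-6)
  expect_equal(bb$Q, 6.1, tolerance = 0.01)
  expect_equal(bb$beta, 6.1, tolerance = 0.02)
  expect_error(enhancement_factor(21, 9.5, 0), "positive")
})

test_that("diffusive flux is linear in the disequilibrium and in k", {
  f <- function(cw, ceq, k, beta = 1, gas = "CO2")
    diffusive_flux(gas, cw, ceq, k, beta)$flux_mgC_m2_d
  expect_equal(f(10, 10, 2), 0)
  expect_equal(f(20, 10, 2), 2 * f(15, 10, 2), tolerance = 1e-12)
  expect_equal(f(0, 10, 2), -f(20, 10, 2), tolerance = 1e-12)  # linear in C_w - C_eq
  expect_equal(f(20, 0, 4), 2 * f(20, 0, 2), tolerance = 1e-12)
  expect_equal(f(20, 0, 2, beta = 3), 3 * f(20, 0, 2), tolerance = 1e-12)
  # sign convention: evasion positive, invasion negative
  expect_gt(f(20, 10, 2), 0)
  expect_lt(f(5, 10, 2), 0)
  # explicit unit chain: 1 umol/L excess at 1 cm/h = 0.24 * 12.011 mg C/m2/d
  expect_equal(f(1, 0, 1), 0.24 * 12.011, tolerance = 1e-12)
  # enhancement rejected for non-CO2 gases
  expect_error(diffusive_flux("CH4", 151, 0, 1.36, beta = 2),
               "CO2 only")
})

test_that("flux ratios across k600 models equal the k600 ratios at fixed beta", {
  ft <- flux_table(c(CH4 = 151, CO2 = 1), temp_C = 21, u10 = 2,
                   elevation_m = 1884)
  for (g in c("CH4", "CO2")) {
    sub <- ft[ft$gas == g, ]
    expect_equal(sub$flux_mgC_m2_d / sub$flux_mgC_m2_d[1],
                 sub$k600_cm_h / sub$k600_cm_h[1], tolerance = 1e-12)
  }
  # the printed-table identity: 1137/591 matches 2.769/1.44 to 3 sig figs
  ch4 <- ft[ft$gas == "CH4", ]
  expect_equal(signif(ch4$flux_mgC_m2_d[ch4$model == "cole_caraco"] /
                      ch4$flux_mgC_m2_d[ch4$model == "crusius_wanninkhof"], 3),
               signif(2.769 / 1.44, 3))
})

test_that("flux table reports both enhancement pathways for CO2", {
  ft <- flux_table(c(CO2 = 1), temp_C = 21, u10 = 2, elevation_m = 1884,
                   pH = 9.5)
  expect_true(all(c("flux_mgC_m2_d", "flux_enhanced_mgC_m2_d") %in% names(ft)))
  expect_true(all(ft$beta > 1))
  expect_true(all(abs(ft$flux_enhanced_mgC_m2_d) > abs(ft$flux_mgC_m2_d)))
  expect_equal(ft$flux_enhanced_mgC_m2_d / ft$flux_mgC_m2_d, ft$beta,
               tolerance = 1e-12)
})

test_that("oxygen saturation has the expected magnitude and monotonicities", {
  expect_equal(oxygen_saturation(21), 8.9, tolerance = 0.01)
  # salting out: strictly decreasing in salinity
  sals <- seq(0, 35, by = 5)
  o2 <- vapply(sals, function(s) oxygen_saturation(21, s), numeric(1))
  expect_true(all(diff(o2) < 0))
  # linear in station pressure
  expect_equal(oxygen_saturation(21, 0, 0.5), oxygen_saturation(21) / 2,
               tolerance = 1e-12)
  # colder water holds more oxygen
  expect_gt(oxygen_saturation(5), oxygen_saturation(30))
})
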