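# Thin-boundary-layer (TBL) diffusive gas exchange across the water-air
# interface: flux = beta * k_i * (C_w - C_eq), with the transfer velocity
# k_i obtained from a wind-based k600 model and Schmidt-number scaling, the
# equilibrium concentration from gas solubility and atmospheric partial
# pressure, and beta the chemical enhancement of CO2 invasion at high pH.

.K600_MODELS <- c("crusius_wanninkhof", "cole_caraco", "nightingale")

#' Schmidt number of CO2 or CH4 in fresh water
#'
#' Fourth-order polynomial fits (Wanninkhof 1992) in temperature:
#' \deqn{Sc_{CO2} = 2116.8 - 136.25T + 4.7353T^2 - 0.09231T^3 + 0.0007555T^4}
#' \deqn{Sc_{CH4} = 2101.2 - 131.54T + 4.4931T^2 - 0.08676T^3 + 0.00070663T^4}
#' with `T` in deg C; the fits are valid for 0-40 deg C.
#'
#' @param gas `"CO2"` or `"CH4"`.
#' @param temp_C Water temperature, deg C (vectorised).
#' @param out_of_range `"error"` (default) or `"warn"` when `temp_C` falls
#'   outside the 0-40 deg C fit range.
#' @return Dimensionless Schmidt number (kinematic viscosity / diffusivity).
#' @examples
#' schmidt_number("CO2", 21) # ~635.9
#' schmidt_number("CH4", 21) # ~654.3
#' @export
schmidt_number <- function(gas = c("CO2", "CH4"), temp_C,
                           out_of_range = c("error", "warn")) {
  gas <- match.arg(gas)
  out_of_range <- match.arg(out_of_range)
  stopifnot(is.numeric(temp_C))
  if (any(temp_C < 0 | temp_C > 40)) {
    msg <- "temp_C outside the 0-40 degC Schmidt polynomial fit range"
    if (out_of_range == "error") stop(msg) else warning(msg)
  }
  cf <- switch(gas,
    CO2 = c(2116.8, -136.25, 4.7353, -0.09231, 0.0007555),
    CH4 = c(2101.2, -131.54, 4.4931, -0.08676, 0.00070663))
  cf[1] + cf[2] * temp_C + cf[3] * temp_C^2 + cf[4] * temp_C^3 + cf[5] * temp_C^4
}

#' Wind-based k600 gas transfer velocity
#'
#' Registry of empirical relations between wind speed at 10 m (`U10`) and
#' the gas transfer velocity normalised to Schmidt number 600:
#' \describe{
#'   \item{`crusius_wanninkhof`}{`k600 = 0.72 U10`}
#'   \item{`cole_caraco`}{`k600 = 0.215 U10^1.7 + 2.07`}
#'   \item{`nightingale`}{`k600 = 0.23 U10^2 + 0.1 U10`}
#' }
#'
#' @param model One of the registry names above.
#' @param u10 Wind speed at 10 m height, m s^-1 (vectorised).
#' @return k600 in cm h^-1.
#' @examples
#' k600_model("cole_caraco", 2) # ~2.769 cm/h
#' @export
k600_model <- function(model, u10) {
  if (!is.character(model) || length(model) != 1 || !model %in% .K600_MODELS) {
    stop("unknown k600 model; valid models: ",
         paste(.K600_MODELS, collapse = ", "))
  }
  stopifnot(is.numeric(u10), all(u10 >= 0))
  switch(model,
    crusius_wanninkhof = 0.72 * u10,
    cole_caraco = 0.215 * u10^1.7 + 2.07,
    nightingale = 0.23 * u10^2 + 0.1 * u10)
}

#' Schmidt-number scaling of the transfer velocity
#'
#' `k_i = k600 * (Sc/600)^x` with the surface-roughness exponent
#' `x = -0.67` for wind speeds below 3 m s^-1 (smooth surface) and
#' `x = -0.5` at or above 3 m s^-1 (the boundary itself is assigned to the
#' rough regime for continuity with increasing wind).
#'
#' @param k600 Transfer velocity at Sc = 600, cm h^-1.
#' @param sc Schmidt number of the gas at the water temperature.
#' @param u10 Wind speed at 10 m, m s^-1 (selects the exponent).
#' @return Gas-specific transfer velocity, cm h^-1.
#' @examples
#' transfer_velocity(1.44, schmidt_number("CH4", 21), u10 = 2)
#' @export
transfer_velocity <- function(k600, sc, u10) {
  stopifnot(all(k600 > 0), all(sc > 0), is.numeric(u10))
  x <- ifelse(u10 < 3, -0.67, -0.5)
  k600 * (sc / 600)^x
}

#' Gas solubility in water
#'
#' Molar solubility (mol L^-1 atm^-1) as a function of temperature and
#' salinity. CO2 uses the Weiss (1974) K0 fit; CH4 and O2 use the Bunsen
#' coefficient fits of Wiesenburg & Guinasso (1979) and Weiss (1970)
#' respectively, divided by the molar gas volume 22.414 L mol^-1 (STP).
#'
#' @param gas `"CO2"`, `"CH4"` or `"O2"`.
#' @param temp_C Water temperature, deg C.
#' @param salinity Practical salinity (default 0, fresh water).
#' @return Solubility in mol L^-1 atm^-1.
#' @examples
#' gas_solubility("CO2", 21) # ~0.0378 mol/L/atm
#' gas_solubility("CH4", 21) # ~1.5e-3 mol/L/atm
#' @export
gas_solubility <- function(gas = c("CO2", "CH4", "O2"), temp_C, salinity = 0) {
  gas <- match.arg(gas)
  stopifnot(is.numeric(temp_C), is.numeric(salinity), all(salinity >= 0))
  T <- .celsius_to_kelvin(temp_C)
  th <- T / 100
  if (gas == "CO2") {
    # Weiss 1974, K0 in mol L^-1 atm^-1
    lnK0 <- -58.0931 + 90.5069 / th + 22.294 * log(th) +
      salinity * (0.027766 - 0.025888 * th + 0.0050578 * th^2)
    return(exp(lnK0))
  }
  bunsen <- switch(gas,
    # Wiesenburg & Guinasso 1979, Bunsen coefficient
    CH4 = exp(-68.8862 + 101.4956 / th + 28.7314 * log(th) +
                salinity * (-0.076146 + 0.043970 * th - 0.0068672 * th^2)),
    # Weiss 1970, Bunsen coefficient
    O2 = exp(-58.3877 + 85.8079 / th + 23.8439 * log(th) +
               salinity * (-0.034892 + 0.015568 * th - 0.0019387 * th^2)))
  bunsen / 22.414
}

#' Dissolved concentration at equilibrium with the atmosphere
#'
#' `C_eq = solubility(T, S) * x_atm * P_station`, with the atmospheric dry
#' mole fraction `x_atm` applied to the barometric station pressure (dry
#' pressure convention; no water-vapour correction — see the vignette for
#' the resulting percent-level sensitivity).
#'
#' @param gas `"CO2"`, `"CH4"` or `"O2"`.
#' @param temp_C Water temperature, deg C.
#' @param mole_fraction Atmospheric dry mole fraction (e.g. `410e-6` for
#'   410 ppm CO2).
#' @param pressure_atm Station pressure, atm (see [station_pressure()]).
#' @param salinity Practical salinity (default 0).
#' @return Equilibrium concentration, umol L^-1.
#' @examples
#' equilibrium_concentration("CO2", 21, 410e-6, station_pressure(1884))
#' @export
equilibrium_concentration <- function(gas, temp_C, mole_fraction,
                                      pressure_atm = 1, salinity = 0) {
  stopifnot(mole_fraction >= 0, mole_fraction < 1, pressure_atm > 0)
  sol <- gas_solubility(gas, temp_C, salinity)
  sol * mole_fraction * pressure_atm * 1e6
}

#' Chemical enhancement factor for CO2 invasion at high pH
#'
#' In alkaline water, CO2 crossing the diffusive boundary layer reacts by
#' hydration (`CO2 + H2O -> H2CO3`) and hydroxylation (`CO2 + OH- -> HCO3-`),
#' steepening the CO2 gradient and enhancing the flux by the factor
#' \deqn{\beta = \tau / \left[(\tau - 1) + \tanh(Q)/Q\right], \quad
#'       Q = (r\tau/D)^{1/2}\, D / k_{CO2}}
#' (Hoover-Berkshire film-reaction model) where `D` is the CO2 molecular
#' diffusivity `D = 14.6836e-5 * ((273.15 + t)/217.2056 - 1)^1.997` cm2 s^-1
#' (Zeebe fit), `r = r1 + r2 Kw/aH` the combined pseudo-first-order reaction
#' rate, and `tau = 1 + aH^2/(K1 K2 + K1 aH)` the equilibrium partitioning
#' term. `beta >= 1` always; `beta -> 1` as `k -> Inf`.
#'
#' @param temp_C Water temperature, deg C.
#' @param pH pH (`aH = 10^-pH`).
#' @param k_co2_cm_h CO2 transfer velocity, cm h^-1 (must be > 0).
#' @param constants Optional [carbonate_constants()] override.
#' @param r1,r2 Optional rate-constant overrides: CO2 hydration rate, s^-1,
#'   and hydroxylation rate, L mol^-1 s^-1 (defaults are temperature-
#'   dependent literature fits).
#' @return An object of class `"enhancement_result"`: list with `beta`,
#'   `tau`, `r`, `r1`, `r2`, `D_cm2_s`, `Q`, `k_co2_cm_s`.
#' @examples
#' enhancement_factor(21, pH = 9.5, k_co2_cm_h = 1.385)
#' @export
enhancement_factor <- function(temp_C, pH, k_co2_cm_h,
                               constants = NULL, r1 = NULL, r2 = NULL) {
  stopifnot(is.numeric(temp_C), pH > 0, pH < 14)
  if (k_co2_cm_h <= 0) {
    stop("k_co2_cm_h must be positive: beta is unbounded in the k -> 0 limit")
  }
  if (is.null(constants)) constants <- carbonate_constants(temp_C)
  rates <- .co2_rate_constants(temp_C)
  if (is.null(r1)) r1 <- rates$r1
  if (is.null(r2)) r2 <- rates$r2
  stopifnot(r1 > 0, r2 > 0)

  aH <- 10^(-pH)
  D <- 14.6836e-5 * ((273.15 + temp_C) / 217.2056 - 1)^1.997
  r <- r1 + r2 * constants$Kw / aH
  tau <- 1 + aH^2 / (constants$K1 * constants$K2 + constants$K1 * aH)
  k_cm_s <- k_co2_cm_h / 3600
  Q <- sqrt(r * tau / D) * D / k_cm_s
  beta <- tau / ((tau - 1) + tanh(Q) / Q)
  structure(list(beta = beta, tau = tau, r = r, r1 = r1, r2 = r2,
                 D_cm2_s = D, Q = Q, k_co2_cm_s = k_cm_s,
                 pH = pH, temp_C = temp_C),
            class = "enhancement_result")
}

#' @export
print.enhancement_result <- function(x, ...) {
  cat(sprintf("CO2 chemical enhancement beta = %.3f (tau = %.5f, Q = %.3f)\n",
              x$beta, x$tau, x$Q))
  cat(sprintf("  r = %.4g s^-1 (r1 %.4g s^-1, r2 %.4g L/mol/s), D = %.4g cm2/s, pH %.2f, %.1f degC\n",
              x$r, x$r1, x$r2, x$D_cm2_s, x$pH, x$temp_C))
  invisible(x)
}

#' Water-air diffusive gas flux (thin boundary layer model)
#'
#' `Phi = beta * k_i * (C_w - C_eq)`, converted to carbon mass flux:
#' k in cm h^-1 is scaled by 0.24 to m d^-1, concentrations in umol L^-1
#' equal mmol m^-3, and mmol of gas carry 12.011 mg C. Positive fluxes are
#' water-to-air (evasion). Chemical enhancement applies to CO2 only; for
#' any other gas `beta` must be 1.
#'
#' @param gas Gas species id (e.g. `"CH4"`, `"CO2"`).
#' @param c_w Dissolved concentration in surface water, umol L^-1.
#' @param c_eq Atmospheric equilibrium concentration, umol L^-1.
#' @param k_cm_h Gas-specific transfer velocity, cm h^-1.
#' @param beta Chemical enhancement factor (default 1); either a number or
#'   an [enhancement_factor()] result.
#' @param model Optional k600 model id recorded for provenance.
#' @param k600,sc Optional provenance values recorded in the result.
#' @return An object of class `"flux_result"`: list with `flux_mgC_m2_d`
#'   and all inputs.
#' @examples
#' k <- transfer_velocity(k600_model("cole_caraco", 2), schmidt_number("CH4", 21), 2)
#' diffusive_flux("CH4", c_w = 151, c_eq = 0, k_cm_h = k) # ~1137 mg C/m2/d
#' @export
diffusive_flux <- function(gas, c_w, c_eq, k_cm_h, beta = 1,
                           model = NA_character_, k600 = NA_real_,
                           sc = NA_real_) {
  if (inherits(beta, "enhancement_result")) beta <- beta$beta
  stopifnot(is.numeric(c_w), is.numeric(c_eq), k_cm_h > 0, beta >= 1)
  if (!identical(gas, "CO2") && beta != 1) {
    stop("chemical enhancement applies to CO2 only; beta must be 1 for ", gas)
  }
  flux <- beta * (k_cm_h * 0.24) * (c_w - c_eq) * .MM[["C"]]
  structure(list(gas = gas, flux_mgC_m2_d = flux,
                 c_w = c_w, c_eq = c_eq, k_cm_h = k_cm_h, beta = beta,
                 model = model, k600 = k600, sc = sc),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  dir <- if (x$flux_mgC_m2_d >= 0) "water -> air" else "air -> water"
  cat(sprintf("%s diffusive flux: %.1f mg C m^-2 d^-1 (%s)\n",
              x$gas, x$flux_mgC_m2_d, dir))
  cat(sprintf("  k = %.3f cm/h, beta = %.3f, C_w = %.3g, C_eq = %.3g umol/L%s\n",
              x$k_cm_h, x$beta, x$c_w, x$c_eq,
              if (is.na(x$model)) "" else paste0(", model ", x$model)))
  invisible(x)
}

#' Water-air flux table across the k600 model registry
#'
#' Convenience wrapper computing the CH4 and CO2 diffusive fluxes for every
#' registered k600 relation at one set of surface conditions. CO2 fluxes are
#' reported on two pathways: `beta = 1` (no enhancement; column
#' `flux_mgC_m2_d`) and, when `pH` is supplied, with the Hoover-Berkshire
#' enhancement (`flux_enhanced_mgC_m2_d`).
#'
#' @param c_w Named numeric vector of surface concentrations, umol L^-1,
#'   with names among `"CH4"`, `"CO2"`.
#' @param temp_C Surface water temperature, deg C.
#' @param u10 Wind speed at 10 m, m s^-1.
#' @param elevation_m Site elevation, m (sets station pressure).
#' @param x_atm Named atmospheric dry mole fractions; default
#'   `c(CO2 = 410e-6, CH4 = 1.87e-6)`.
#' @param salinity Practical salinity for solubility and Sc (default 0).
#' @param pH Optional surface pH; when given, the CO2 enhanced-flux column
#'   is added.
#' @param models k600 model ids (default: the full registry).
#' @return A data.frame with one row per (model, gas): columns `model`,
#'   `gas`, `k600_cm_h`, `sc`, `k_cm_h`, `beta`, `c_w_umol_L`,
#'   `c_eq_umol_L`, `flux_mgC_m2_d`, and `flux_enhanced_mgC_m2_d` if `pH`
#'   was supplied.
#' @examples
#' flux_table(c(CH4 = 151, CO2 = 1), temp_C = 21, u10 = 2, elevation_m = 1884)
#' @export
flux_table <- function(c_w, temp_C = 21, u10 = 2, elevation_m = 0,
                       x_atm = c(CO2 = 410e-6, CH4 = 1.87e-6),
                       salinity = 0, pH = NULL, models = .K600_MODELS) {
  stopifnot(is.numeric(c_w), !is.null(names(c_w)),
            all(names(c_w) %in% c("CH4", "CO2")))
  p_stn <- station_pressure(elevation_m)
  rows <- list()
  for (m in models) {
    k6 <- k600_model(m, u10)
    for (g in names(c_w)) {
      sc <- schmidt_number(g, temp_C)
      k <- transfer_velocity(k6, sc, u10)
      ceq <- equilibrium_concentration(g, temp_C, unname(x_atm[g]), p_stn,
                                       salinity)
      fl <- diffusive_flux(g, unname(c_w[g]), ceq, k, beta = 1,
                           model = m, k600 = k6, sc = sc)
      row <- data.frame(model = m, gas = g, k600_cm_h = k6, sc = sc,
                        k_cm_h = k, beta = 1, c_w_umol_L = unname(c_w[g]),
                        c_eq_umol_L = ceq, flux_mgC_m2_d = fl$flux_mgC_m2_d)
      if (!is.null(pH)) {
        if (g == "CO2") {
          b <- enhancement_factor(temp_C, pH, k)
          row$flux_enhanced_mgC_m2_d <-
            diffusive_flux(g, unname(c_w[g]), ceq, k, beta = b)$flux_mgC_m2_d
          row$beta <- b$beta
        } else {
          row$flux_enhanced_mgC_m2_d <- row$flux_mgC_m2_d
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Oxygen saturation concentration
#'
#' Dissolved-oxygen concentration at equilibrium with the atmosphere
#' (Benson & Krause 1984 fit, as adopted by USGS), scaled linearly by
#' station pressure. Salinity enters through the standard salting-out term.
#'
#' @param temp_C Water temperature, deg C.
#' @param salinity Practical salinity (default 0).
#' @param pressure_atm Station pressure, atm (default 1).
#' @return Saturation concentration, mg L^-1.
#' @examples
#' oxygen_saturation(21) # ~8.9 mg/L at sea level
#' oxygen_saturation(21, salinity = 10, pressure_atm = station_pressure(1884))
#' @export
oxygen_saturation <- function(temp_C, salinity = 0, pressure_atm = 1) {
  stopifnot(is.numeric(temp_C), all(salinity >= 0), all(pressure_atm > 0))
  T <- .celsius_to_kelvin(temp_C)
  lnC <- -139.34411 + 1.575701e5 / T - 6.642308e7 / T^2 +
    1.2438e10 / T^3 - 8.621949e11 / T^4 -
    salinity * (0.017674 - 10.754 / T + 2140.7 / T^2)
  exp(lnC) * pressure_atm
}
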