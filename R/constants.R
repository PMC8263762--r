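# Physical constants and published empirical fits used across the package.
# Every fit carries a source tag so defaults can be audited and overridden.

# Ideal gas constant, L atm mol^-1 K^-1
.R_GAS <- 0.0820574

# Molar masses, g mol^-1
.MM <- c(C = 12.011, HCO3 = 61.017, CO3 = 60.009)

.celsius_to_kelvin <- function(t_C) t_C + 273.15

#' Barometric station pressure at elevation
#'
#' Isothermal barometric formula `P = exp(-z / H)` atm with scale height
#' `H = 8400` m, adequate for converting sea-level atmospheric mole
#' fractions to partial pressures at tropical high-elevation lakes.
#'
#' @param elevation_m Site elevation above sea level, m.
#' @param scale_height_m Atmospheric scale height, m (default 8400).
#' @return Station pressure in atm.
#' @examples
#' station_pressure(1884) # ~0.80 atm
#' @export
station_pressure <- function(elevation_m, scale_height_m = 8400) {
  stopifnot(is.numeric(elevation_m), elevation_m >= 0, scale_height_m > 0)
  exp(-elevation_m / scale_height_m)
}

#' Freshwater carbonate-system equilibrium constants
#'
#' First and second dissociation constants of carbonic acid and the ion
#' product of water, on the molar freshwater (infinite-dilution) scale:
#' K1 from Harned & Davis (1943), K2 from Harned & Scholes (1941), Kw from
#' Harned & Owen (1958). No ionic-strength correction is applied; see the
#' methods vignette for the implications in hypersaline bottom waters.
#'
#' @param temp_C Water temperature, deg C.
#' @return A list with components `K1`, `K2` (mol L^-1), `Kw` (mol^2 L^-2),
#'   `temp_C`, and a `source` tag. `K1 > K2` always holds.
#' @examples
#' carbonate_constants(21) # pK1 ~ 6.38, pK2 ~ 10.37
#' @export
carbonate_constants <- function(temp_C) {
  stopifnot(is.numeric(temp_C), temp_C > -5, temp_C < 60)
  T <- .celsius_to_kelvin(temp_C)
  K1 <- 10^(-3404.71 / T + 14.8435 - 0.032786 * T)
  K2 <- 10^(-2902.39 / T + 6.4980 - 0.02379 * T)
  Kw <- 10^(-4470.99 / T + 6.0875 - 0.01706 * T)
  list(K1 = K1, K2 = K2, Kw = Kw, temp_C = temp_C,
       source = "Harned & Davis 1943 (K1); Harned & Scholes 1941 (K2); Harned & Owen 1958 (Kw); freshwater, molar scale")
}

# CO2 hydration (r1, s^-1) and hydroxylation (r2, L mol^-1 s^-1) rate
# constants. r1: Johnson (1982); r2: log10 kOH = 13.635 - 2895/T fit to the
# kinetics compiled for the CO2 + OH- pathway (Schulz et al. 2006 family,
# zero ionic strength).
.co2_rate_constants <- function(temp_C) {
  T <- .celsius_to_kelvin(temp_C)
  list(r1 = exp(1246.98 - 6.19e4 / T - 183.0 * log(T)),
       r2 = 10^(13.635 - 2895 / T),
       source = "Johnson 1982 (r1); log10 kOH = 13.635 - 2895/T (r2)")
}
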