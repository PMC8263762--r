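# Carbonate-system speciation at high pH and the 13C mass balance that
# recovers the isotopic composition of dissolved CO2 from that of total
# dissolved inorganic carbon (TDIC), assuming chemical and isotopic
# equilibrium among CO2(aq), HCO3- and CO3^2-.

#' Equilibrium carbon isotope enrichment factors
#'
#' Temperature-dependent equilibrium enrichment factors between the
#' dissolved carbonate species, in per mil:
#' \deqn{\epsilon_{HCO3-CO2} = 9866/T - 24.12}
#' \deqn{\epsilon_{CO3-HCO3} = 1.85 - 666/T}
#' with `T` in Kelvin.
#'
#' @param temp_K Temperature in Kelvin (vectorised).
#' @return A list with numeric components `eps_hco3_co2` and `eps_co3_hco3`
#'   (per mil vs V-PDB scale differences).
#' @examples
#' enrichment_factors(294.15) # ~9.42 and ~-0.414 per mil at 21 degC
#' @export
enrichment_factors <- function(temp_K) {
  stopifnot(is.numeric(temp_K), all(temp_K > 0))
  list(eps_hco3_co2 = 9866 / temp_K - 24.12,
       eps_co3_hco3 = 1.85 - 666 / temp_K)
}

#' delta13C of dissolved CO2 from delta13C of TDIC
#'
#' Isotope mass balance over the carbonate system: given the measured
#' delta13C of total dissolved inorganic carbon and the concentrations of
#' the three carbon species, the delta13C of dissolved CO2 is
#' \deqn{\delta^{13}C_{CO2} = \delta^{13}C_{TDIC}
#'   - \frac{[HCO_3^-]}{TDIC}\,\epsilon_{HCO3-CO2}
#'   - \frac{[CO_3^{2-}]}{TDIC}\,(\epsilon_{CO3-HCO3}+\epsilon_{HCO3-CO2})}
#' with enrichment factors from [enrichment_factors()]. Valid under the
#' assumption of chemical and isotopic equilibrium among the species.
#'
#' @param hco3_mmol,co3_mmol,co2_mmol Species concentrations, mmol L^-1.
#'   `hco3_mg_L`/`co3_mg_L` may be given instead (converted with molar
#'   masses 61.017 and 60.009 g mol^-1).
#' @param d13c_tdic delta13C of TDIC, per mil vs V-PDB.
#' @param temp_K Temperature, Kelvin. Must lie in (270, 330), the validity
#'   range of the enrichment-factor fits.
#' @param hco3_mg_L,co3_mg_L Optional mass-concentration inputs, mg L^-1.
#' @return An object of class `"d13c_co2"`: a list with `d13c_co2` (per mil),
#'   the species fractions, the enrichment factors, and the inputs.
#' @examples
#' # bottom water of an equatorial soda lake: HCO3 9523 mg/L, CO3 2196 mg/L,
#' # CO2 126 umol/L, d13C-TDIC +10.7 permil, 21 degC
#' d13c_co2_from_tdic(hco3_mg_L = 9523, co3_mg_L = 2196, co2_mmol = 0.126,
#'                    d13c_tdic = 10.7, temp_K = 294.15)
#' @export
d13c_co2_from_tdic <- function(hco3_mmol = NULL, co3_mmol = NULL, co2_mmol,
                               d13c_tdic, temp_K,
                               hco3_mg_L = NULL, co3_mg_L = NULL) {
  if (is.null(hco3_mmol)) {
    stopifnot(!is.null(hco3_mg_L))
    hco3_mmol <- hco3_mg_L / .MM[["HCO3"]]
  }
  if (is.null(co3_mmol)) {
    stopifnot(!is.null(co3_mg_L))
    co3_mmol <- co3_mg_L / .MM[["CO3"]]
  }
  stopifnot(is.numeric(co2_mmol), is.numeric(d13c_tdic), is.numeric(temp_K),
            hco3_mmol >= 0, co3_mmol >= 0, co2_mmol >= 0,
            temp_K > 270, temp_K < 330)
  tdic <- hco3_mmol + co3_mmol + co2_mmol
  if (tdic <= 0) {
    stop("undefined state: TDIC = CO2 + HCO3 + CO3 must be positive")
  }
  eps <- enrichment_factors(temp_K)
  f_hco3 <- hco3_mmol / tdic
  f_co3 <- co3_mmol / tdic
  d13c <- d13c_tdic -
    f_hco3 * eps$eps_hco3_co2 -
    f_co3 * (eps$eps_co3_hco3 + eps$eps_hco3_co2)
  structure(list(
    d13c_co2 = d13c, d13c_tdic = d13c_tdic,
    f_co2 = co2_mmol / tdic, f_hco3 = f_hco3, f_co3 = f_co3,
    eps_hco3_co2 = eps$eps_hco3_co2, eps_co3_hco3 = eps$eps_co3_hco3,
    tdic_mmol = tdic, temp_K = temp_K
  ), class = "d13c_co2")
}

#' @export
print.d13c_co2 <- function(x, ...) {
  cat(sprintf("delta13C-CO2 = %.2f permil vs V-PDB  (from delta13C-TDIC = %.2f permil)\n",
              x$d13c_co2, x$d13c_tdic))
  cat(sprintf("  TDIC %.3f mmol/L; fractions CO2 %.4f | HCO3 %.4f | CO3 %.4f\n",
              x$tdic_mmol, x$f_co2, x$f_hco3, x$f_co3))
  cat(sprintf("  eps(HCO3-CO2) %.3f permil, eps(CO3-HCO3) %.3f permil at %.2f K\n",
              x$eps_hco3_co2, x$eps_co3_hco3, x$temp_K))
  invisible(x)
}

#' Closed-form carbonate speciation at a given pH
#'
#' Distributes inorganic carbon among CO2(aq), HCO3- and CO3^2- from the
#' hydrogen-ion activity `aH = 10^-pH` and the dissociation constants K'1
#' and K'2. The ionisation fractions are
#' `alpha0 : alpha1 : alpha2 = aH^2 : K1*aH : K1*K2` (normalised to 1).
#' The pool is anchored by one known quantity: total DIC, the measured
#' (HCO3, CO3) pair, or total alkalinity `AT = [HCO3] + 2[CO3] + [OH] - [H]`.
#'
#' @param pH pH (free scale; `aH = 10^-pH`).
#' @param tdic_mmol Total dissolved inorganic carbon, mmol L^-1.
#' @param hco3_mmol,co3_mmol Measured carbonate species pair, mmol L^-1
#'   (their sum anchors the pool; the returned values are re-speciated at
#'   the given pH).
#' @param alkalinity_meq Total alkalinity, meq L^-1.
#' @param temp_C Temperature, deg C, for the equilibrium constants.
#' @param constants Optional list overriding [carbonate_constants()]
#'   (components `K1`, `K2`, `Kw`, mol-based).
#' @return A list with `co2_mmol`, `hco3_mmol`, `co3_mmol`, `tdic_mmol`, the
#'   ionisation fractions `alpha0/alpha1/alpha2`, and `constants`.
#' @examples
#' speciate_carbonate(pH = 9.5, tdic_mmol = 190, temp_C = 21)
#' @export
speciate_carbonate <- function(pH, tdic_mmol = NULL,
                               hco3_mmol = NULL, co3_mmol = NULL,
                               alkalinity_meq = NULL,
                               temp_C = 21, constants = NULL) {
  stopifnot(is.numeric(pH), pH > 0, pH < 14)
  if (is.null(constants)) constants <- carbonate_constants(temp_C)
  K1 <- constants$K1; K2 <- constants$K2; Kw <- constants$Kw
  stopifnot(K1 > 0, K2 > 0, K1 > K2)
  aH <- 10^(-pH)
  denom <- aH^2 + K1 * aH + K1 * K2
  alpha <- c(aH^2, K1 * aH, K1 * K2) / denom

  if (!is.null(tdic_mmol)) {
    stopifnot(tdic_mmol > 0)
    dic <- tdic_mmol
  } else if (!is.null(hco3_mmol) && !is.null(co3_mmol)) {
    stopifnot(hco3_mmol > 0, co3_mmol >= 0)
    # anchor: the measured HCO3 + CO3 equals the speciated HCO3 + CO3
    dic <- (hco3_mmol + co3_mmol) / (alpha[2] + alpha[3])
  } else if (!is.null(alkalinity_meq)) {
    stopifnot(alkalinity_meq > 0)
    # carbonate alkalinity = AT - [OH-] + [H+]  (mol-based, then mmol)
    ca <- alkalinity_meq / 1000 - Kw / aH + aH
    if (ca <= 0) {
      stop("infeasible state: alkalinity and pH imply non-positive carbonate alkalinity")
    }
    dic <- 1000 * ca / (alpha[2] + 2 * alpha[3])
  } else {
    stop("one of tdic_mmol, (hco3_mmol, co3_mmol), or alkalinity_meq is required")
  }

  list(co2_mmol = alpha[1] * dic,
       hco3_mmol = alpha[2] * dic,
       co3_mmol = alpha[3] * dic,
       tdic_mmol = dic,
       alpha0 = alpha[1], alpha1 = alpha[2], alpha2 = alpha[3],
       pH = pH, constants = constants)
}

#' pH implied by a measured HCO3/CO3 pair
#'
#' Inverts the second dissociation equilibrium:
#' `pH = pK'2 + log10([CO3]/[HCO3])`.
#'
#' @param hco3_mmol,co3_mmol Species concentrations, mmol L^-1 (any common
#'   unit works; only the ratio matters).
#' @param temp_C Temperature, deg C.
#' @param constants Optional override as in [speciate_carbonate()].
#' @return Implied pH.
#' @export
ph_from_carbonate_ratio <- function(hco3_mmol, co3_mmol, temp_C = 21,
                                    constants = NULL) {
  stopifnot(hco3_mmol > 0, co3_mmol > 0)
  if (is.null(constants)) constants <- carbonate_constants(temp_C)
  -log10(constants$K2) + log10(co3_mmol / hco3_mmol)
}
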