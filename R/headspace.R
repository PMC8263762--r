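# Henry's-law partitioning of flask headspace measurements: from the gas
# mole fraction measured in the headspace of an equilibrated sampling
# flask to dissolved, gaseous and total moles and the equivalent in-situ
# aqueous concentration.

#' Default Henry's-law constants
#'
#' Package defaults for the gases measured in equilibrated flask
#' headspaces, as molar solubilities (mol L^-1 atm^-1) at 25 deg C, from
#' the Sander (2015) compilation of Henry's-law constants. The table is a
#' plain data.frame and can be replaced wholesale or per-row.
#'
#' @return data.frame with columns `gas`, `value_mol_L_atm`, `temp_C`,
#'   `source`.
#' @examples
#' henry_defaults()
#' @export
henry_defaults <- function() {
  data.frame(
    gas = c("CH4", "CO2", "N2", "Ar", "He", "H2", "O2"),
    value_mol_L_atm = c(1.4e-3, 3.4e-2, 6.4e-4, 1.4e-3, 3.8e-4, 7.8e-4, 1.3e-3),
    temp_C = 25,
    source = "Sander 2015 compilation (water, 298.15 K)"
  )
}

#' Look up a Henry's-law constant
#'
#' @param gas Gas species id.
#' @param table Constant table in the [henry_defaults()] layout.
#' @return A list with `gas`, `value` (mol L^-1 atm^-1), `temp_C`, `source`.
#' @export
henry_constant <- function(gas, table = henry_defaults()) {
  i <- match(gas, table$gas)
  if (is.na(i)) stop("no Henry constant for gas ", gas, "; available: ",
                     paste(table$gas, collapse = ", "))
  stopifnot(table$value_mol_L_atm[i] > 0)
  list(gas = gas, value = table$value_mol_L_atm[i],
       temp_C = table$temp_C[i], source = table$source[i])
}

#' Partition a flask headspace measurement into dissolved and gaseous moles
#'
#' A water sample equilibrates with the headspace of a sampling flask; the
#' gas mole fraction measured in the headspace is mapped back to amounts:
#' headspace moles from the ideal-gas law
#' (`n_g = x P V_hs / (R T)`, `R = 0.0820574` L atm mol^-1 K^-1), aqueous
#' concentration from Henry's law (`c_aq = K_H x P`), dissolved moles
#' `n_l = c_aq V_water`, and total `n_t = n_l + n_g` (exact mass balance).
#' The equivalent partial pressure is recomputed from `n_t` by the
#' ideal-gas law over the full flask volume (headspace + water volume as
#' the gas-accessible reference volume; a documented convention).
#'
#' @param gas Gas species id.
#' @param headspace_mole_fraction Dry mole fraction of the gas in the
#'   headspace, in `[0, 1]`.
#' @param flask_volume_L,water_volume_L Flask and water-sample volumes, L
#'   (`0 < water < flask`).
#' @param temp_C Equilibration/analysis temperature, deg C.
#' @param headspace_pressure_atm Headspace total pressure, atm (default 1:
#'   flask at atmospheric pressure at analysis time).
#' @param henry Henry constant as returned by [henry_constant()]; defaults
#'   to the package table entry for `gas`.
#' @param temp_tolerance_C Allowed mismatch between `temp_C` and the Henry
#'   constant's reference temperature before a provenance warning is
#'   recorded (default 5).
#' @return An object of class `"flask_partition"`: list with
#'   `headspace_moles`, `dissolved_moles`, `total_moles` (mol),
#'   `aqueous_umol_L`, `partial_pressure_atm`, geometry, and `warnings`.
#' @examples
#' partition_flask("CH4", headspace_mole_fraction = 0.01,
#'                 flask_volume_L = 0.25, water_volume_L = 0.15, temp_C = 21)
#' @export
partition_flask <- function(gas, headspace_mole_fraction,
                            flask_volume_L, water_volume_L, temp_C,
                            headspace_pressure_atm = 1,
                            henry = henry_constant(gas),
                            temp_tolerance_C = 5) {
  stopifnot(headspace_mole_fraction >= 0, headspace_mole_fraction <= 1,
            flask_volume_L > 0, water_volume_L > 0,
            water_volume_L < flask_volume_L,
            headspace_pressure_atm > 0, henry$value > 0)
  warn <- character()
  if (abs(henry$temp_C - temp_C) > temp_tolerance_C) {
    warn <- sprintf("Henry constant referenced at %.1f degC but sample at %.1f degC",
                    henry$temp_C, temp_C)
    warning(warn)
  }
  T_K <- .celsius_to_kelvin(temp_C)
  v_hs <- flask_volume_L - water_volume_L
  p_i <- headspace_mole_fraction * headspace_pressure_atm
  n_g <- p_i * v_hs / (.R_GAS * T_K)
  c_aq <- henry$value * p_i                     # mol L^-1
  n_l <- c_aq * water_volume_L
  n_t <- n_l + n_g
  structure(list(gas = gas,
                 headspace_moles = n_g, dissolved_moles = n_l,
                 total_moles = n_t,
                 aqueous_umol_L = c_aq * 1e6,
                 partial_pressure_atm = n_t * .R_GAS * T_K / flask_volume_L,
                 headspace_mole_fraction = headspace_mole_fraction,
                 headspace_pressure_atm = headspace_pressure_atm,
                 flask_volume_L = flask_volume_L,
                 water_volume_L = water_volume_L,
                 temp_C = temp_C, henry = henry, warnings = warn),
            class = "flask_partition")
}

#' @export
print.flask_partition <- function(x, ...) {
  cat(sprintf("<flask_partition> %s: n_g %.4g, n_l %.4g, n_t %.4g mol\n",
              x$gas, x$headspace_moles, x$dissolved_moles, x$total_moles))
  cat(sprintf("  c_aq %.4g umol/L, p_i %.4g atm (flask %.3g L, water %.3g L, %.1f degC)\n",
              x$aqueous_umol_L, x$partial_pressure_atm,
              x$flask_volume_L, x$water_volume_L, x$temp_C))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' Partition a table of flask measurements
#'
#' Applies [partition_flask()] row-wise to a flask table with columns
#' `sample_id, gas, mole_fraction, headspace_pressure_atm, flask_vol_L,
#' water_vol_L, temp_C` (missing pressure defaults to 1 atm).
#'
#' @param flasks data.frame in the layout above.
#' @param henry_table Henry constant table ([henry_defaults()] layout).
#' @return data.frame: the input plus `n_g_mol`, `n_l_mol`, `n_t_mol`,
#'   `aqueous_umol_L`, `partial_pressure_atm`.
#' @export
partition_flask_table <- function(flasks, henry_table = henry_defaults()) {
  stopifnot(is.data.frame(flasks),
            all(c("sample_id", "gas", "mole_fraction", "flask_vol_L",
                  "water_vol_L", "temp_C") %in% names(flasks)))
  if (!"headspace_pressure_atm" %in% names(flasks)) {
    flasks$headspace_pressure_atm <- 1
  }
  res <- lapply(seq_len(nrow(flasks)), function(i) {
    p <- partition_flask(flasks$gas[i], flasks$mole_fraction[i],
                         flasks$flask_vol_L[i], flasks$water_vol_L[i],
                         flasks$temp_C[i], flasks$headspace_pressure_atm[i],
                         henry = henry_constant(flasks$gas[i], henry_table))
    data.frame(n_g_mol = p$headspace_moles, n_l_mol = p$dissolved_moles,
               n_t_mol = p$total_moles, aqueous_umol_L = p$aqueous_umol_L,
               partial_pressure_atm = p$partial_pressure_atm)
  })
  cbind(flasks, do.call(rbind, res))
}
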