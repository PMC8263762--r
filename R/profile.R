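# Depth-profile container and diagnostics for a stratified lake water
# column: chemocline/oxycline location, depletion-depth extrapolation and
# chlorophyll-a conversion. Depths are stored positive downward, in m.

# canonical column set accepted by the CSV reader/writer
.PROFILE_COLS <- c("depth_m", "temp_C", "pH", "cond_uS_cm", "DO_mg_L",
                   "CH4_umol_L", "CO2_umol_L", "N2_umol_L", "Ar_umol_L",
                   "He_umol_L", "H2_umol_L",
                   "d13C_CH4", "d13C_CO2", "d13C_TDIC",
                   "HCO3_mg_L", "CO3_mg_L", "DOC_mg_L", "chla_ug_L")

.NONNEG_COLS <- c("cond_uS_cm", "DO_mg_L", "CH4_umol_L", "CO2_umol_L",
                  "N2_umol_L", "Ar_umol_L", "He_umol_L", "H2_umol_L",
                  "HCO3_mg_L", "CO3_mg_L", "DOC_mg_L", "chla_ug_L")

#' Construct a depth profile
#'
#' A `depth_profile` is a data.frame of per-depth physico-chemical
#' measurements with a mandatory `depth_m` column (strictly increasing,
#' non-negative, positive downward) and any subset of the canonical
#' measurement columns (`temp_C`, `pH`, `cond_uS_cm`, `DO_mg_L`,
#' `CH4_umol_L`, `CO2_umol_L`, `N2_umol_L`, `Ar_umol_L`, `He_umol_L`,
#' `H2_umol_L`, `d13C_CH4`, `d13C_CO2`, `d13C_TDIC`, `HCO3_mg_L`,
#' `CO3_mg_L`, `DOC_mg_L`, `chla_ug_L`). Missing cells stay `NA`;
#' diagnostics skip depths with missing required fields and report which
#' depths they used.
#'
#' @param data data.frame with `depth_m` plus measurement columns.
#' @param station_id Station/date label (attribute).
#' @return A validated object of classes `c("depth_profile", "data.frame")`.
#' @examples
#' depth_profile(data.frame(depth_m = c(0, 1, 2), DO_mg_L = c(3.6, 3.2, 0.1)))
#' @export
depth_profile <- function(data, station_id = "station") {
  stopifnot(is.data.frame(data))
  out <- as.data.frame(data)
  class(out) <- c("depth_profile", "data.frame")
  attr(out, "station_id") <- station_id
  validate_depth_profile(out)
  out
}

#' Validate a depth profile
#'
#' Checks the container invariants: at least one record; depths numeric,
#' non-negative and strictly increasing; concentrations non-negative where
#' present; pH within (0, 14). Errors name the offending rows.
#'
#' @param profile A [depth_profile()].
#' @return The profile, invisibly, if valid.
#' @export
validate_depth_profile <- function(profile) {
  stopifnot(is.data.frame(profile))
  if (!"depth_m" %in% names(profile)) stop("column 'depth_m' is required")
  z <- profile$depth_m
  if (length(z) < 1) stop("profile must contain at least one depth record")
  if (!is.numeric(z) || anyNA(z)) stop("depth_m must be numeric and complete")
  if (any(z < 0)) stop("depths must be >= 0 (positive downward); rows: ",
                       paste(which(z < 0), collapse = ", "))
  if (is.unsorted(z, strictly = TRUE)) {
    bad <- which(diff(z) <= 0) + 1L
    stop("depths must be strictly increasing; offending rows: ",
         paste(bad, collapse = ", "))
  }
  for (cc in intersect(.NONNEG_COLS, names(profile))) {
    v <- profile[[cc]]
    if (any(v < 0, na.rm = TRUE)) {
      stop(cc, " must be non-negative; rows: ",
           paste(which(!is.na(v) & v < 0), collapse = ", "))
    }
  }
  if ("pH" %in% names(profile)) {
    v <- profile$pH
    if (any(v <= 0 | v >= 14, na.rm = TRUE)) {
      stop("pH must lie in (0, 14); rows: ",
           paste(which(!is.na(v) & (v <= 0 | v >= 14)), collapse = ", "))
    }
  }
  invisible(profile)
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> station '%s': %d depths, %.1f-%.1f m\n",
              attr(x, "station_id"), nrow(x), min(x$depth_m), max(x$depth_m)))
  vars <- setdiff(names(x), "depth_m")
  cat("  variables:", if (length(vars)) paste(vars, collapse = ", ") else "(none)", "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a depth profile from CSV
#'
#' Reads a comma-separated, decimal-point, UTF-8 table with a header row.
#' Columns are taken as-is when they already use the canonical names; a
#' `col_map` renames file columns (`c(depth_m = "prof_depth", ...)`).
#' Unmapped, non-canonical columns are ignored; empty cells become `NA`.
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping canonical names
#'   (names) to file column names (values).
#' @param station_id Station label; defaults to the file name.
#' @return A validated [depth_profile()].
#' @export
read_depth_profile <- function(path, col_map = NULL, station_id = NULL) {
  if (!file.exists(path)) stop("cannot read profile file: ", path)
  raw <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    stopifnot(!is.null(names(col_map)), all(names(col_map) %in% .PROFILE_COLS))
    missing <- setdiff(unname(col_map), names(raw))
    if (length(missing)) stop("mapped columns absent from file: ",
                              paste(missing, collapse = ", "))
    for (std in names(col_map)) raw[[std]] <- raw[[col_map[[std]]]]
  }
  keep <- intersect(.PROFILE_COLS, names(raw))
  if (!"depth_m" %in% keep) stop("no 'depth_m' column after mapping")
  out <- raw[keep]
  for (cc in keep) {
    if (!is.numeric(out[[cc]])) {
      suppressWarnings(v <- as.numeric(out[[cc]]))
      if (anyNA(v) && !all(is.na(v) == (is.na(out[[cc]]) | out[[cc]] == ""))) {
        stop("column ", cc, " contains non-numeric cells")
      }
      out[[cc]] <- v
    }
  }
  depth_profile(out, station_id = station_id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a depth profile to CSV
#'
#' Inverse of [read_depth_profile()]: canonical column names, comma
#' separator, decimal point, missing cells empty. Numeric cells round-trip
#' to the precision given by `digits`.
#'
#' @param profile A [depth_profile()].
#' @param path Output file path.
#' @param digits Significant digits written (default 15: round-trips
#'   doubles exactly through text).
#' @return `path`, invisibly.
#' @export
write_depth_profile <- function(profile, path, digits = 15) {
  validate_depth_profile(profile)
  out <- as.data.frame(profile)
  for (cc in names(out)) out[[cc]] <- signif(out[[cc]], digits)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Locate the chemocline and oxycline
#'
#' The chemocline is placed at the midpoint of the depth interval with the
#' largest absolute finite-difference conductivity gradient
#' `|d(cond)/dz|` (ties broken toward the surface). The oxycline is the
#' shallowest interval midpoint where dissolved oxygen crosses below the
#' anoxia threshold. Each depth is then labelled `OSW` (oxic surface
#' water, above the oxycline), `ASW` (anoxic surface water, between
#' oxycline and chemocline) or `BW` (bottom water, below the chemocline).
#' Depths with the required field missing are skipped and reported.
#'
#' @param profile A [depth_profile()] with `cond_uS_cm` and `DO_mg_L`
#'   present at three or more depths each.
#' @param anoxia_threshold_mg_L Dissolved-O2 cutoff defining anoxic water,
#'   mg L^-1 (default 0.5).
#' @return An object of class `"layer_partition"`: list with
#'   `chemocline_depth`, `oxycline_depth` (m), a `labels` data.frame
#'   (`depth_m`, `layer`), and the depths used for each estimate. If
#'   oxygen never crosses the threshold the oxycline is placed at the
#'   chemocline (no ASW layer) and flagged.
#' @examples
#' pr <- depth_profile(data.frame(
#'   depth_m = c(0, 1, 2, 3, 4, 4.5),
#'   cond_uS_cm = c(12000, 12100, 12050, 12080, 33000, 33100),
#'   DO_mg_L = c(3.6, 3.4, 0.1, 0.1, 0.1, 0.1)))
#' locate_layers(pr)
#' @export
locate_layers <- function(profile, anoxia_threshold_mg_L = 0.5) {
  validate_depth_profile(profile)
  stopifnot(anoxia_threshold_mg_L > 0)
  for (req in c("cond_uS_cm", "DO_mg_L")) {
    if (!req %in% names(profile) || sum(!is.na(profile[[req]])) < 3) {
      stop("insufficient data: ", req, " required at >= 3 depths")
    }
  }
  ok_c <- !is.na(profile$cond_uS_cm)
  zc <- profile$depth_m[ok_c]; cond <- profile$cond_uS_cm[ok_c]
  grad <- abs(diff(cond) / diff(zc))
  i <- which.max(grad)                      # which.max takes the first tie
  chemocline <- (zc[i] + zc[i + 1]) / 2

  ok_o <- !is.na(profile$DO_mg_L)
  zo <- profile$depth_m[ok_o]; do_ <- profile$DO_mg_L[ok_o]
  below <- do_ < anoxia_threshold_mg_L
  cross <- which(!below[-length(below)] & below[-1])
  no_oxycline <- length(cross) == 0 && !below[1]
  oxycline <- if (below[1]) {
    (zo[1] + 0) / 2                          # anoxic from the first record
  } else if (length(cross)) {
    (zo[cross[1]] + zo[cross[1] + 1]) / 2
  } else {
    chemocline                               # fully oxic mixolimnion
  }
  if (oxycline > chemocline) {
    warning("estimated oxycline below the chemocline; clamping to the chemocline")
    oxycline <- chemocline
  }

  layer <- ifelse(profile$depth_m < oxycline, "OSW",
                  ifelse(profile$depth_m < chemocline, "ASW", "BW"))
  structure(list(chemocline_depth = chemocline,
                 oxycline_depth = oxycline,
                 no_oxycline = no_oxycline,
                 anoxia_threshold_mg_L = anoxia_threshold_mg_L,
                 labels = data.frame(depth_m = profile$depth_m, layer = layer),
                 depths_used_conductivity = zc,
                 depths_used_oxygen = zo),
            class = "layer_partition")
}

#' @export
print.layer_partition <- function(x, ...) {
  cat(sprintf("<layer_partition> oxycline %.2f m, chemocline %.2f m%s\n",
              x$oxycline_depth, x$chemocline_depth,
              if (x$no_oxycline) " (no O2 crossing: oxycline set to chemocline)" else ""))
  cat("  layers:", paste(sprintf("%.1fm=%s", x$labels$depth_m, x$labels$layer),
                         collapse = " "), "\n")
  invisible(x)
}

#' Extrapolated gas depletion depth
#'
#' Fits an ordinary least-squares line of concentration versus depth over
#' a depth window and extrapolates to zero concentration — the depth at
#' which the gas would vanish if the observed vertical decrease continued
#' unchanged toward the surface. A negative crossing (above the surface)
#' is returned as-is and flagged. If the concentration does not decrease
#' toward the surface (slope of concentration vs depth not positive) the
#' result is flagged `no_depletion` and no crossing is returned.
#'
#' @param profile A [depth_profile()].
#' @param gas Gas species: `"CH4"`, `"CO2"`, `"N2"`, `"Ar"`, `"He"` or
#'   `"H2"` (selects column `<gas>_umol_L`).
#' @param fit_window Length-2 numeric: depth range (m, inclusive) of points
#'   entering the fit.
#' @return A list with `depth_m` (zero crossing, `NA` when flagged),
#'   `no_depletion`, `above_surface`, `slope_umol_L_m`, `intercept_umol_L`,
#'   and `depths_used`.
#' @examples
#' pr <- depth_profile(data.frame(depth_m = c(3, 4.5), CH4_umol_L = c(201, 615)))
#' depletion_depth(pr, "CH4", c(3, 4.5)) # crossing at ~2.27 m
#' @export
depletion_depth <- function(profile, gas = "CH4", fit_window) {
  validate_depth_profile(profile)
  col <- paste0(gas, "_umol_L")
  if (!col %in% names(profile)) stop("profile has no column ", col)
  stopifnot(is.numeric(fit_window), length(fit_window) == 2)
  fit_window <- sort(fit_window)
  sel <- !is.na(profile[[col]]) &
    profile$depth_m >= fit_window[1] & profile$depth_m <= fit_window[2]
  if (sum(sel) < 2) stop("need >= 2 concentration values inside fit_window")
  z <- profile$depth_m[sel]
  conc <- profile[[col]][sel]
  fit <- stats::lm(conc ~ z)
  b <- unname(stats::coef(fit))              # intercept, slope
  if (!is.finite(b[2]) || b[2] <= 0) {
    return(list(depth_m = NA_real_, no_depletion = TRUE,
                above_surface = FALSE, slope_umol_L_m = b[2],
                intercept_umol_L = b[1], depths_used = z))
  }
  z0 <- -b[1] / b[2]
  list(depth_m = z0, no_depletion = FALSE, above_surface = z0 < 0,
       slope_umol_L_m = b[2], intercept_umol_L = b[1], depths_used = z)
}

#' Chlorophyll-a concentration from extract absorbance
#'
#' Beer-Lambert conversion of the red-peak absorbance (663-665 nm) of a
#' 90% acetone pigment extract to a sample concentration:
#' `chla = A / (coefficient * path_length) * 1e6 * (V_extract / V_filtered)`
#' with the specific absorption coefficient expressed in L g^-1 cm^-1
#' (84.1 for chlorophyll-a in 90% acetone), so `A / (coeff * l)` is in
#' g L^-1 of extract.
#'
#' @param peak_absorbance Blank-corrected peak absorbance (dimensionless,
#'   >= 0).
#' @param path_length_cm Cuvette path length, cm.
#' @param extract_volume_mL Extract volume, mL.
#' @param filtered_volume_L Filtered water-sample volume, L.
#' @param coefficient_L_g_cm Specific absorption coefficient, L g^-1 cm^-1
#'   (default 84.1).
#' @return Chlorophyll-a concentration in the water sample, ug L^-1.
#' @examples
#' chlorophyll_from_absorbance(0.841, 1, extract_volume_mL = 10,
#'                             filtered_volume_L = 0.1) # 1000 ug/L
#' @export
chlorophyll_from_absorbance <- function(peak_absorbance, path_length_cm = 1,
                                        extract_volume_mL, filtered_volume_L,
                                        coefficient_L_g_cm = 84.1) {
  stopifnot(peak_absorbance >= 0, path_length_cm > 0, extract_volume_mL > 0,
            filtered_volume_L > 0, coefficient_L_g_cm > 0)
  extract_g_L <- peak_absorbance / (coefficient_L_g_cm * path_length_cm)
  extract_g_L * 1e6 * (extract_volume_mL / 1000) / filtered_volume_L
}
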