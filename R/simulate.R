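# Synthetic stratified-lake generator. Emulates a two-layer meromictic
# soda-lake water column — logistic transitions of conductivity and
# dissolved gases across the chemocline, a sharp oxycline — plus a
# molecular-formula table in which planted fractions of aliphatic-like and
# aromatic-like formulas (anti-)covary with the CH4 profile, and flask
# headspace rows that partition back to a prescribed concentration.
# Every generator is a pure function of (scenario, seed): each draws from
# its own named stream (seed + fixed offset) and restores the caller's RNG
# state, so adding a generator never perturbs existing fixtures.

.with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed + offset)
  force(expr)
}

.logistic <- function(z, center, width) 1 / (1 + exp(-(z - center) / width))

# logistic transition rescaled to run exactly 0 -> 1 over the depth grid,
# so layer end-member values are hit exactly at the top and bottom depths
.logistic01 <- function(z, center, width) {
  L <- .logistic(z, center, width)
  (L - L[1]) / (L[length(L)] - L[1])
}

#' Define a synthetic stratified-lake scenario
#'
#' Bundles every knob of the synthetic generators with defaults shaped on
#' an equatorial meromictic crater soda lake: seven sampling depths over
#' 0-4.5 m, oxycline at 1.5 m, chemocline at 3.5 m, CH4 rising from
#' ~151 (surface) to ~615 umol L^-1 (bottom), CO2 from 1 to ~120
#' umol L^-1, conductivity stepping from 12 to 33 mS cm^-1, pH 9.6 -> 9.5,
#' oxygen 3.6 -> 0.1 mg L^-1, and a slight upward CH4 drift within the
#' mixolimnion. The DOM block plants a fraction of aliphatic-like formulas
#' covarying with CH4 and a fraction of aromatic-like formulas
#' anti-covarying, at a configurable coupling noise.
#'
#' @param seed Integer seed driving all generator streams.
#' @param depths Sampling depths, m (strictly increasing).
#' @param oxycline_m,chemocline_m Layer boundaries, m.
#' @param transition_width_m Logistic transition scale across the
#'   chemocline, m.
#' @param oxycline_width_m Logistic transition scale of dissolved oxygen
#'   across the oxycline, m (sharper than the chemocline by default).
#' @param ch4_umol_L,co2_umol_L,cond_uS_cm,temp_C,pH,do_mg_L Length-2
#'   vectors `c(surface, bottom)` of layer end-member values.
#' @param ch4_surface_gradient Fractional CH4 increase per metre inside the
#'   mixolimnion (keeps the profile strictly monotone, as observed in
#'   surface waters; default 0.03).
#' @param noise_rel_sd Gaussian relative standard deviation applied
#'   multiplicatively to every measured variable (default 0.02, the
#'   percent-level reproducibility of field sensors and GC analyses; set 0
#'   for noise-free profiles).
#' @param n_formulas Named vector: formulas generated per class (defaults
#'   `c(aliphatic = 200, aromatic = 100, other = 100)`).
#' @param planted_pos_aliphatic Fraction of aliphatic-like formulas planted
#'   to covary with CH4 (default 0.275).
#' @param planted_neg_aromatic Fraction of aromatic-like formulas planted
#'   to anti-covary (default 0.34).
#' @param dom_coupling_sd Gaussian sd of the planted abundance signal
#'   around the rank-uniform CH4 transform (unit-range scale; default
#'   0.03, i.e. tightly coupled molecules).
#' @return An object of class `"lake_scenario"` (a list of the above).
#' @examples
#' sc <- lake_scenario(seed = 1)
#' @export
lake_scenario <- function(seed = 1,
                          depths = c(0, 0.5, 1, 2, 3, 4, 4.5),
                          oxycline_m = 1.5, chemocline_m = 3.5,
                          transition_width_m = 0.25,
                          oxycline_width_m = 0.15,
                          ch4_umol_L = c(151, 615),
                          co2_umol_L = c(1, 120),
                          cond_uS_cm = c(12000, 33000),
                          temp_C = c(22.4, 20.5),
                          pH = c(9.61, 9.47),
                          do_mg_L = c(3.6, 0.1),
                          ch4_surface_gradient = 0.03,
                          noise_rel_sd = 0.02,
                          n_formulas = c(aliphatic = 200, aromatic = 100,
                                         other = 100),
                          planted_pos_aliphatic = 0.275,
                          planted_neg_aromatic = 0.34,
                          dom_coupling_sd = 0.03) {
  stopifnot(length(depths) >= 1, !is.unsorted(depths, strictly = TRUE),
            all(depths >= 0),
            oxycline_m >= min(depths), oxycline_m <= max(depths),
            chemocline_m >= oxycline_m, chemocline_m <= max(depths),
            transition_width_m > 0, oxycline_width_m > 0, noise_rel_sd >= 0,
            planted_pos_aliphatic >= 0, planted_pos_aliphatic <= 1,
            planted_neg_aromatic >= 0, planted_neg_aromatic <= 1,
            dom_coupling_sd >= 0)
  structure(list(seed = as.integer(seed), depths = depths,
                 oxycline_m = oxycline_m, chemocline_m = chemocline_m,
                 transition_width_m = transition_width_m,
                 oxycline_width_m = oxycline_width_m,
                 ch4_umol_L = ch4_umol_L, co2_umol_L = co2_umol_L,
                 cond_uS_cm = cond_uS_cm, temp_C = temp_C, pH = pH,
                 do_mg_L = do_mg_L,
                 ch4_surface_gradient = ch4_surface_gradient,
                 noise_rel_sd = noise_rel_sd, n_formulas = n_formulas,
                 planted_pos_aliphatic = planted_pos_aliphatic,
                 planted_neg_aromatic = planted_neg_aromatic,
                 dom_coupling_sd = dom_coupling_sd),
            class = "lake_scenario")
}

#' @export
print.lake_scenario <- function(x, ...) {
  cat(sprintf("<lake_scenario> seed %d: %d depths (%.1f-%.1f m), oxycline %.1f m, chemocline %.1f m\n",
              x$seed, length(x$depths), min(x$depths), max(x$depths),
              x$oxycline_m, x$chemocline_m))
  cat(sprintf("  CH4 %g->%g, CO2 %g->%g umol/L; noise rel sd %g\n",
              x$ch4_umol_L[1], x$ch4_umol_L[2], x$co2_umol_L[1],
              x$co2_umol_L[2], x$noise_rel_sd))
  invisible(x)
}

# noise-free water-column state of a scenario
.profile_truth <- function(sc) {
  z <- sc$depths
  Lc <- .logistic01(z, sc$chemocline_m, sc$transition_width_m)
  Lo <- .logistic01(z, sc$oxycline_m, sc$oxycline_width_m)
  # mixolimnion CH4 drifts gently upward with depth, then blends into the
  # bottom-water end member across the chemocline (strictly monotone)
  mix <- sc$ch4_umol_L[1] * (1 + sc$ch4_surface_gradient * pmin(z, sc$chemocline_m))
  ch4 <- mix * (1 - Lc) + sc$ch4_umol_L[2] * Lc
  data.frame(
    depth_m = z,
    temp_C = sc$temp_C[1] + diff(sc$temp_C) * Lc,
    pH = sc$pH[1] + diff(sc$pH) * Lc,
    cond_uS_cm = sc$cond_uS_cm[1] + diff(sc$cond_uS_cm) * Lc,
    DO_mg_L = sc$do_mg_L[1] + diff(sc$do_mg_L) * Lo,
    CH4_umol_L = ch4,
    CO2_umol_L = sc$co2_umol_L[1] + diff(sc$co2_umol_L) * Lc)
}

#' Generate a synthetic depth profile
#'
#' Builds the noise-free water-column state of a [lake_scenario()]
#' (logistic transitions across the oxycline for O2 and across the
#' chemocline for temperature, pH, conductivity, CH4 and CO2), applies
#' multiplicative Gaussian noise, truncates concentrations at zero, and
#' returns both the noisy profile and the ground truth. Deterministic for
#' a fixed scenario seed; the caller's RNG state is untouched.
#'
#' @param scenario A [lake_scenario()].
#' @return list with `profile` (noisy [depth_profile()]), `truth`
#'   (noise-free [depth_profile()]), and `n_truncated` (noise draws
#'   clipped at zero).
#' @examples
#' sim <- simulate_profile(lake_scenario(seed = 7))
#' locate_layers(sim$profile)
#' @export
simulate_profile <- function(scenario) {
  stopifnot(inherits(scenario, "lake_scenario"))
  truth <- .profile_truth(scenario)
  .with_stream(scenario$seed, 101L, {
    noisy <- truth
    n_trunc <- 0L
    for (cc in setdiff(names(truth), "depth_m")) {
      v <- truth[[cc]] * (1 + stats::rnorm(nrow(truth), 0, scenario$noise_rel_sd))
      if (cc %in% c("cond_uS_cm", "DO_mg_L", "CH4_umol_L", "CO2_umol_L")) {
        n_trunc <- n_trunc + sum(v < 0)
        v <- pmax(v, 0)
      }
      noisy[[cc]] <- v
    }
    list(profile = depth_profile(noisy, station_id = "synthetic"),
         truth = depth_profile(truth, station_id = "synthetic-truth"),
         n_truncated = n_trunc)
  })
}

# rejection-sample element counts for one intended class
.sample_formula <- function(class) {
  for (i in 1:200) {
    C <- sample(12:40, 1)
    f <- switch(class,
      aliphatic = data.frame(C = C, H = round(C * stats::runif(1, 1.55, 2.0)),
                             N = 0, O = round(C * stats::runif(1, 0.02, 0.3)),
                             S = 0),
      aromatic = data.frame(C = C, H = round(C * stats::runif(1, 0.4, 0.85)),
                            N = 0, O = round(C * stats::runif(1, 0.05, 0.35)),
                            S = 0),
      other = data.frame(C = C, H = round(C * stats::runif(1, 1.05, 1.4)),
                         N = 0, O = round(C * stats::runif(1, 0.35, 0.7)),
                         S = 0))
    got <- as.character(classify_formulas(f)$class)
    want <- c(aliphatic = "aliphatic-like", aromatic = "aromatic-like",
              other = "other")[[class]]
    if (got == want) return(f)
  }
  stop("rejection sampling failed for class ", class)   # not reachable in practice
}

#' Generate a synthetic molecular-formula abundance table
#'
#' Draws element counts per class by rejection sampling in van Krevelen
#' space, then assigns per-depth relative abundances: a planted fraction
#' of the aliphatic-like formulas follows a monotone (rank-uniform)
#' transform of the profile's CH4 concentrations plus Gaussian coupling
#' noise; a planted fraction of the aromatic-like formulas follows the
#' negated transform; all remaining formulas get independent uniform
#' abundances (null). Abundances are strictly positive, so every formula
#' passes the all-depths-present filter.
#'
#' @param scenario A [lake_scenario()].
#' @param profile A [depth_profile()] with >= 4 depths and a complete
#'   `CH4_umol_L` column (typically `simulate_profile(scenario)$truth` or
#'   `$profile`).
#' @return list with `formulas` (data.frame: `formula_id`, element counts,
#'   `ab_d<depth>` columns) and `truth` (data.frame: `formula_id`,
#'   `class_intended`, `planted` in {"pos", "neg", "null"}).
#' @examples
#' sc <- lake_scenario(seed = 3)
#' sim <- simulate_profile(sc)
#' ft <- generate_formula_table(sc, sim$truth)
#' table(ft$truth$planted)
#' @export
generate_formula_table <- function(scenario, profile) {
  stopifnot(inherits(scenario, "lake_scenario"),
            inherits(profile, "depth_profile"),
            nrow(profile) >= 4, "CH4_umol_L" %in% names(profile),
            !anyNA(profile$CH4_umol_L))
  ch4 <- profile$CH4_umol_L
  nd <- length(ch4)
  s <- (rank(ch4) - 1) / (nd - 1)            # rank-uniform monotone transform
  .with_stream(scenario$seed, 202L, {
    nf <- scenario$n_formulas
    rows <- list(); truth <- list(); id <- 0L
    for (cl in c("aliphatic", "aromatic", "other")) {
      n <- nf[[cl]]
      n_planted <- round(n * switch(cl,
        aliphatic = scenario$planted_pos_aliphatic,
        aromatic = scenario$planted_neg_aromatic,
        other = 0))
      for (j in seq_len(n)) {
        id <- id + 1L
        planted <- if (j <= n_planted) {
          if (cl == "aliphatic") "pos" else "neg"
        } else "null"
        ab <- switch(planted,
          pos = 0.5 + s + stats::rnorm(nd, 0, scenario$dom_coupling_sd),
          neg = 0.5 + (1 - s) + stats::rnorm(nd, 0, scenario$dom_coupling_sd),
          null = stats::runif(nd, 0.2, 1.2))
        ab <- pmax(ab, 1e-6)                  # keep strictly positive
        el <- .sample_formula(cl)
        row <- cbind(data.frame(formula_id = sprintf("f%04d", id)), el,
                     as.data.frame(as.list(stats::setNames(
                       ab, paste0("ab_d", profile$depth_m)))))
        rows[[id]] <- row
        truth[[id]] <- data.frame(formula_id = row$formula_id,
                                  class_intended = cl, planted = planted)
      }
    }
    list(formulas = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Generate a flask headspace row for a known dissolved concentration
#'
#' Exact inverse of [partition_flask()]: produces the headspace mole
#' fraction that an equilibrated flask would show for a prescribed true
#' aqueous concentration, `x = c_aq / (K_H * P)`. Deterministic (no
#' measurement noise), so partitioning the returned row recovers the input
#' concentration to machine precision.
#'
#' @param gas Gas species id.
#' @param aqueous_umol_L True dissolved concentration, umol L^-1.
#' @param flask_volume_L,water_volume_L Flask geometry, L.
#' @param temp_C Equilibration temperature, deg C.
#' @param headspace_pressure_atm Headspace pressure, atm (default 1).
#' @param henry Henry constant ([henry_constant()] layout).
#' @return One-row data.frame in the [partition_flask_table()] input
#'   layout.
#' @examples
#' row <- generate_flask_sample("CH4", 151, 0.25, 0.15, 21)
#' partition_flask_table(row)$aqueous_umol_L # 151
#' @export
generate_flask_sample <- function(gas, aqueous_umol_L,
                                  flask_volume_L, water_volume_L, temp_C,
                                  headspace_pressure_atm = 1,
                                  henry = henry_constant(gas)) {
  stopifnot(aqueous_umol_L >= 0, flask_volume_L > 0,
            water_volume_L > 0, water_volume_L < flask_volume_L)
  x <- (aqueous_umol_L * 1e-6) / (henry$value * headspace_pressure_atm)
  if (x > 1) stop("concentration implies headspace mole fraction > 1; ",
                  "reduce aqueous_umol_L or raise pressure")
  data.frame(sample_id = paste0("synthetic_", gas), gas = gas,
             mole_fraction = x,
             headspace_pressure_atm = headspace_pressure_atm,
             flask_vol_L = flask_volume_L, water_vol_L = water_volume_L,
             temp_C = temp_C)
}
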