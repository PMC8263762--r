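# Independent oracles kept deliberately separate from the package code
# paths they check.

# all permutations of 1..n as a list (plain recursion, no shared code with
# the package's permutation matrix)
perms_list <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in perms_list(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# brute-force two-sided exact permutation p for Spearman rho (average ranks)
brute_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  rhos <- vapply(perms_list(length(x)),
                 function(p) cor(rx[p], ry), numeric(1))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

# independent step-by-step evaluation of the Hoover-Berkshire enhancement
# model from its printed pieces, taking every constant as an input
oracle_beta <- function(temp_C, pH, k_cm_h, K1, K2, Kw, r1, r2) {
  aH <- 10^(-pH)
  D <- 14.6836e-5 * ((273.15 + temp_C) / 217.2056 - 1)^1.997
  r <- r1 + r2 * Kw / aH
  tau <- 1 + aH^2 / (K1 * K2 + K1 * aH)
  k <- k_cm_h / 3600
  q <- sqrt(r * tau / D) * (D / k)
  tau / ((tau - 1) + tanh(q) / q)
}

# a small fully populated water-column fixture in the field layout
fixture_profile <- function() {
  depth_profile(data.frame(
    depth_m = c(0, 0.5, 1, 2, 3, 4, 4.5),
    temp_C = c(22.4, 22.3, 22.1, 21.8, 21.2, 20.7, 20.5),
    pH = c(9.61, 9.60, 9.58, 9.55, 9.51, 9.48, 9.47),
    cond_uS_cm = c(12000, 12050, 12080, 12120, 12400, 32500, 33000),
    DO_mg_L = c(3.6, 3.4, 2.8, 0.1, 0.1, 0.1, 0.1),
    CH4_umol_L = c(151, 153, 156, 160, 201, 540, 615),
    CO2_umol_L = c(1, 1.2, 1.5, 3, 20, 110, 126)))
}
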