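# Van Krevelen classification of FT-ICR-MS molecular formulas and the
# Spearman rank-correlation screen of per-depth formula abundances against
# the CH4 depth profile. Significance is binned on raw two-sided p-values
# at 0.005 and 0.01, mirroring the conventional red/orange/blue/magenta
# van Krevelen colouring; an optional BH-FDR column is exposed separately.

#' Modified aromaticity index (AImod)
#'
#' `AImod = (1 + C - O/2 - S - H/2) / (C - O/2 - N - S)`, the
#' double-bond-equivalent-based aromaticity measure for molecular formulas
#' in which half the oxygen is assumed carbonyl-bound. A non-positive
#' denominator (no carbon skeleton left) yields 0 by convention.
#'
#' @param C,H,N,O,S Element counts (vectorised; `C >= 1`).
#' @return AImod, dimensionless.
#' @examples
#' aromaticity_index(C = 10, H = 6, N = 0, O = 1, S = 0) # ~0.79
#' @export
aromaticity_index <- function(C, H, N = 0, O = 0, S = 0) {
  stopifnot(all(C >= 1))
  num <- 1 + C - O / 2 - S - H / 2
  den <- C - O / 2 - N - S
  ifelse(den > 0, num / den, 0)
}

#' Classify molecular formulas in van Krevelen space
#'
#' Default rule set (standard FT-ICR-MS conventions):
#' \describe{
#'   \item{aromatic-like}{`AImod > 0.5`}
#'   \item{aliphatic-like}{`H/C >= 1.5` and `AImod <= 0.5`}
#'   \item{other}{the remainder}
#' }
#' Both thresholds are configurable. Classification depends only on the
#' element ratios, so it is invariant under scaling all counts by a common
#' integer.
#'
#' @param formulas data.frame with integer columns `C`, `H` and optionally
#'   `N`, `O`, `S` (absent elements default to 0).
#' @param hc_aliphatic H/C threshold for aliphatic-like (default 1.5).
#' @param ai_aromatic AImod threshold for aromatic-like (default 0.5).
#' @return The input with columns `H_C`, `O_C`, `AImod` and `class`
#'   (factor: aliphatic-like / aromatic-like / other) appended.
#' @examples
#' classify_formulas(data.frame(C = c(10, 10, 10), H = c(20, 6, 14),
#'                              O = c(1, 1, 5)))
#' @export
classify_formulas <- function(formulas, hc_aliphatic = 1.5,
                              ai_aromatic = 0.5) {
  stopifnot(is.data.frame(formulas), all(c("C", "H") %in% names(formulas)))
  for (el in c("N", "O", "S")) if (!el %in% names(formulas)) formulas[[el]] <- 0
  stopifnot(all(formulas$C >= 1),
            all(formulas[c("C", "H", "N", "O", "S")] >= 0))
  formulas$H_C <- formulas$H / formulas$C
  formulas$O_C <- formulas$O / formulas$C
  formulas$AImod <- aromaticity_index(formulas$C, formulas$H, formulas$N,
                                      formulas$O, formulas$S)
  formulas$class <- factor(
    ifelse(formulas$AImod > ai_aromatic, "aromatic-like",
           ifelse(formulas$H_C >= hc_aliphatic, "aliphatic-like", "other")),
    levels = c("aliphatic-like", "aromatic-like", "other"))
  formulas
}

# all permutations of 1..n as an n! x n index matrix (n <= 8)
.perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perm_matrix(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

# Spearman rho of y against x using average ranks; NA if either is constant
.spearman_rho <- function(rx, ry) {
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Spearman rank-correlation screen of formula abundances against CH4
#'
#' For every molecular formula present (non-zero abundance) at all depths,
#' computes the Spearman rank correlation between its per-depth relative
#' abundance and the dissolved CH4 concentration, with average-rank tie
#' handling. Two-sided p-values come from the exact permutation null
#' distribution (all `n!` orderings of the covariate) when the number of
#' depths is 8 or fewer, and from the t approximation otherwise. Results
#' are binned as in conventional van Krevelen colouring: `pos_strong`
#' (`rho > 0`, `p < 0.005`), `pos_weak` (`rho > 0`, `0.005 <= p < 0.01`),
#' mirrored for negative, otherwise `ns`. Formulas with zero abundance at
#' any depth are excluded (count reported); formulas with constant
#' abundance have undefined rho and are flagged `ns`.
#'
#' @param formulas data.frame with element counts and per-depth abundance
#'   columns named `ab_*` (one per depth, depth order), or a numeric
#'   matrix/data.frame of abundances only.
#' @param ch4_umol_L Per-depth CH4 concentrations, umol L^-1 (length =
#'   number of abundance columns, >= 4 depths).
#' @param fdr Append a Benjamini-Hochberg `fdr` column (default TRUE).
#' @return data.frame with one row per retained formula: any id/element
#'   columns from the input plus `rho`, `p`, `bin`, `constant`, and
#'   optionally `fdr`. Attributes: `n_excluded` (absent-at-some-depth
#'   count), `n_depths`, `method` ("exact_permutation" or
#'   "t_approximation").
#' @examples
#' ab <- rbind(ab1 = 1:7, ab2 = c(3, 1, 4, 1, 5, 9, 2))
#' colnames(ab) <- paste0("ab_", 1:7)
#' spearman_screen(as.data.frame(ab), ch4_umol_L = c(151, 153, 158, 165, 201, 540, 615))
#' @export
spearman_screen <- function(formulas, ch4_umol_L, fdr = TRUE) {
  if (is.matrix(formulas)) formulas <- as.data.frame(formulas)
  ab_cols <- grep("^ab_", names(formulas), value = TRUE)
  if (length(ab_cols) == 0) {
    ab_cols <- names(formulas)[vapply(formulas, is.numeric, logical(1))]
  }
  ab <- as.matrix(formulas[ab_cols])
  n <- ncol(ab)
  stopifnot(n >= 4, length(ch4_umol_L) == n, all(ab >= 0, na.rm = TRUE))

  present <- apply(ab, 1, function(v) all(!is.na(v) & v > 0))
  n_excluded <- sum(!present)
  keep <- formulas[present, setdiff(names(formulas), ab_cols), drop = FALSE]
  ab <- ab[present, , drop = FALSE]

  rx <- rank(ch4_umol_L)
  exact <- n <= 8
  if (exact) {
    P <- .perm_matrix(n)
    RX <- matrix(rx[P], nrow(P), n)   # every permuted covariate ranking
    RXc <- RX - rowMeans(RX)
    rx_norm <- sqrt(rowSums(RXc^2))
  }

  res <- lapply(seq_len(nrow(ab)), function(i) {
    ry <- rank(ab[i, ])
    rho <- .spearman_rho(rx, ry)
    if (is.na(rho)) {
      return(data.frame(rho = NA_real_, p = NA_real_, bin = "ns",
                        constant = TRUE))
    }
    if (exact) {
      ryc <- ry - mean(ry)
      rho_null <- as.vector(RXc %*% ryc) / (rx_norm * sqrt(sum(ryc^2)))
      p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    bin <- if (p < 0.005) {
      if (rho > 0) "pos_strong" else if (rho < 0) "neg_strong" else "ns"
    } else if (p < 0.01) {
      if (rho > 0) "pos_weak" else if (rho < 0) "neg_weak" else "ns"
    } else "ns"
    data.frame(rho = rho, p = p, bin = bin, constant = FALSE)
  })
  res <- do.call(rbind, res)
  res$bin <- factor(res$bin, levels = c("ns", "pos_strong", "pos_weak",
                                        "neg_strong", "neg_weak"))
  out <- cbind(keep, res)
  if (fdr) out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_depths") <- n
  attr(out, "method") <- if (exact) "exact_permutation" else "t_approximation"
  out
}

#' Per-class fractions of significantly correlated formulas
#'
#' For each van Krevelen class, the percentage of formulas whose abundance
#' correlates significantly (two-sided `p < p_cut`) positively and
#' negatively with CH4. Denominators are class sizes among screened
#' formulas; empty classes report `NA` percentages (undefined, not 0).
#'
#' @param screened A [spearman_screen()] result that carries a `class`
#'   column (e.g. screen run on [classify_formulas()] output), or a
#'   data.frame with columns `class`, `rho`, `p`.
#' @param p_cut Significance cutoff on the raw two-sided p (default 0.01).
#' @return data.frame with one row per class: `class`, `n`, `n_pos`,
#'   `n_neg`, `pct_pos`, `pct_neg`.
#' @export
class_fraction_summary <- function(screened, p_cut = 0.01) {
  stopifnot(is.data.frame(screened), nrow(screened) > 0,
            all(c("class", "rho", "p") %in% names(screened)))
  cls <- factor(screened$class,
                levels = c("aliphatic-like", "aromatic-like", "other"))
  sig <- !is.na(screened$p) & screened$p < p_cut
  res <- lapply(levels(cls), function(cl) {
    sel <- cls == cl
    n <- sum(sel)
    n_pos <- sum(sel & sig & screened$rho > 0, na.rm = TRUE)
    n_neg <- sum(sel & sig & screened$rho < 0, na.rm = TRUE)
    data.frame(class = cl, n = n, n_pos = n_pos, n_neg = n_neg,
               pct_pos = if (n > 0) 100 * n_pos / n else NA_real_,
               pct_neg = if (n > 0) 100 * n_neg / n else NA_real_)
  })
  do.call(rbind, res)
}

#' One-call DOM-CH4 covariation screen
#'
#' Classifies a molecular-formula table, screens every all-depths-present
#' formula against the profile's CH4 concentrations, and summarises the
#' per-class significant fractions.
#'
#' @param formulas data.frame with `C`, `H` (optionally `N`, `O`, `S`) and
#'   per-depth abundance columns `ab_*` in profile depth order.
#' @param profile A [depth_profile()] with a complete `CH4_umol_L` column,
#'   or a numeric vector of per-depth CH4 concentrations.
#' @param ... Passed to [classify_formulas()].
#' @return list with `table` (per-formula screen results incl. class),
#'   `summary` ([class_fraction_summary()]), `n_excluded`.
#' @export
dom_screen <- function(formulas, profile, ...) {
  ch4 <- if (inherits(profile, "depth_profile")) {
    stopifnot("CH4_umol_L" %in% names(profile))
    profile$CH4_umol_L
  } else profile
  stopifnot(is.numeric(ch4), !anyNA(ch4))
  classified <- classify_formulas(formulas, ...)
  screened <- spearman_screen(classified, ch4)
  list(table = screened,
       summary = class_fraction_summary(screened),
       n_excluded = attr(screened, "n_excluded"))
}
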