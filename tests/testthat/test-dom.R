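test_that("aromaticity index and default classification match hand evaluation", {
  df <- classify_formulas(data.frame(C = c(10, 10, 10), H = c(20, 6, 14),
                                     O = c(1, 1, 5)))
  expect_equal(df$H_C, c(2.0, 0.6, 1.4))
  expect_equal(df$O_C, c(0.1, 0.1, 0.5))
  # AImod = (1 + C - O/2 - S - H/2) / (C - O/2 - N - S), by hand
  expect_equal(df$AImod[2], (1 + 10 - 0.5 - 0 - 3) / (10 - 0.5 - 0 - 0),
               tolerance = 1e-12)
  expect_equal(as.character(df$class),
               c("aliphatic-like", "aromatic-like", "other"))
  # non-positive denominator falls back to 0
  expect_equal(aromaticity_index(C = 2, H = 2, O = 8), 0)
})

test_that("classification depends only on composition ratios under count scaling", {
  set.seed(3)
  base <- data.frame(C = sample(5:30, 60, TRUE), H = sample(4:60, 60, TRUE),
                     N = sample(0:2, 60, TRUE), O = sample(0:20, 60, TRUE),
                     S = sample(0:1, 60, TRUE))
  cb <- classify_formulas(base)
  # the H/C and O/C ratios are exactly scale-free; AImod's constant "+1"
  # term decays as 1/k, so class labels are stable for formulas away from
  # the rule boundaries
  den <- cb$C - cb$O / 2 - cb$N - cb$S
  margin <- den > 0 & abs(cb$AImod - 0.5) > 1 / den & abs(cb$H_C - 1.5) > 0.1
  for (k in c(2L, 4L)) {
    ck <- classify_formulas(base * k)
    expect_equal(ck$H_C, cb$H_C, tolerance = 1e-12)
    expect_equal(ck$O_C, cb$O_C, tolerance = 1e-12)
    expect_equal(ck$class[margin], cb$class[margin])
    # AImod converges toward the ratio limit as counts grow
    expect_true(all(abs(ck$AImod - cb$AImod) <= abs(1 - 1 / k) *
                      1 / pmax(cb$C - cb$O / 2 - cb$N - cb$S, 1) + 1e-9))
  }
})

test_that("exact permutation p-values match brute-force enumeration (n <= 7)", {
  set.seed(19)
  for (n in c(4, 5, 6, 7)) {
    x <- runif(n, 100, 700)
    ys <- rbind(runif(n),                        # untied
                sample(c(1, 1, 2, seq_len(n)))[seq_len(n)],  # tied abundances
                sort(runif(n)))                  # monotone
    for (i in seq_len(nrow(ys))) {
      ab <- matrix(ys[i, ], nrow = 1,
                   dimnames = list(NULL, paste0("ab_", seq_len(n))))
      got <- spearman_screen(as.data.frame(ab), x, fdr = FALSE)
      oracle <- brute_spearman_p(x, ys[i, ])
      expect_equal(got$rho, oracle$rho, tolerance = 1e-12)
      expect_equal(got$p, oracle$p, tolerance = 1e-12)
    }
  }
})

test_that("a strictly CH4-monotone abundance over 7 depths is pos_strong", {
  ch4 <- c(151, 153, 156, 160, 201, 540, 615)
  ab <- matrix(c(1, 2, 3, 4, 5, 6, 7), nrow = 1,
               dimnames = list(NULL, paste0("ab_", 1:7)))
  out <- spearman_screen(as.data.frame(ab), ch4)
  expect_equal(out$rho, 1)
  expect_equal(out$p, 2 / 5040, tolerance = 1e-12)
  expect_equal(as.character(out$bin), "pos_strong")
  expect_equal(attr(out, "method"), "exact_permutation")
})

test_that("tie-free exact p agrees with cor.test's exact distribution", {
  set.seed(5)
  for (i in 1:5) {
    x <- sample(100:999, 6)
    y <- runif(6)
    ab <- matrix(y, nrow = 1, dimnames = list(NULL, paste0("ab_", 1:6)))
    got <- spearman_screen(as.data.frame(ab), x, fdr = FALSE)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("screen antisymmetry, presence filter, and degenerate inputs", {
  ch4 <- c(151, 153, 156, 160, 201, 540, 615)
  set.seed(23)
  ab <- matrix(runif(5 * 7, 0.1, 1), 5,
               dimnames = list(NULL, paste0("ab_", 1:7)))
  fwd <- spearman_screen(as.data.frame(ab), ch4, fdr = FALSE)
  rev <- spearman_screen(as.data.frame(ab), rev(ch4), fdr = FALSE)
  # reversing the covariate ordering negates rho and preserves p
  expect_equal(rev$rho, -fwd$rho, tolerance = 1e-12)
  expect_equal(rev$p, fwd$p, tolerance = 1e-12)

  # zero abundance at any depth excludes the formula, and is counted
  ab2 <- ab; ab2[2, 4] <- 0
  out2 <- spearman_screen(as.data.frame(ab2), ch4, fdr = FALSE)
  expect_equal(nrow(out2), 4)
  expect_equal(attr(out2, "n_excluded"), 1)

  # constant abundance: rho undefined, flagged ns
  ab3 <- rbind(ab, rep(0.5, 7))
  out3 <- spearman_screen(as.data.frame(ab3), ch4, fdr = FALSE)
  expect_true(out3$constant[6])
  expect_true(is.na(out3$rho[6]))
  expect_equal(as.character(out3$bin[6]), "ns")

  expect_error(spearman_screen(as.data.frame(ab[, 1:3]), ch4[1:3]))
})

test_that("large-n screening falls back to the t approximation", {
  set.seed(31)
  n <- 12
  ab <- matrix(runif(n), 1, dimnames = list(NULL, paste0("ab_", 1:n)))
  out <- spearman_screen(as.data.frame(ab), runif(n), fdr = FALSE)
  expect_equal(attr(out, "method"), "t_approximation")
  expect_true(out$p > 0 && out$p <= 1)
})

test_that("class fractions use class sizes as denominators", {
  mk <- function(n, n_pos, cl) data.frame(
    class = cl,
    rho = c(rep(0.95, n_pos), rep(0.1, n - n_pos)),
    p = c(rep(0.001, n_pos), rep(0.6, n - n_pos)))
  sc <- rbind(mk(200, 55, "aliphatic-like"), mk(100, 0, "aromatic-like"))
  s <- class_fraction_summary(sc)
  expect_equal(s$pct_pos[s$class == "aliphatic-like"], 27.5)
  expect_equal(s$pct_pos[s$class == "aromatic-like"], 0)
  expect_true(is.na(s$pct_pos[s$class == "other"]))   # empty class: undefined
  # one formula, strongly positive -> 100%
  s1 <- class_fraction_summary(mk(1, 1, "other"))
  expect_equal(s1$pct_pos[s1$class == "other"], 100)
})
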