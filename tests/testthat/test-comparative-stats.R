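fits_frame <- function(proteins, HL, slope_se = 0.01, df = 11) {
  data.frame(protein = proteins, cohort = "X", k = log(2) / HL, HL = HL,
             slope_se = slope_se, df = df, stringsAsFactors = FALSE)
}

test_that("half-life ratios join on protein and detect injected effects", {
  a <- fits_frame(sprintf("P%02d", 1:20), HL = seq(1, 20))
  expect_equal(compute_hl_ratios(a, a)$ratio, rep(1, 20))

  b <- a; b$HL <- a$HL * 1.6; b$k <- a$k / 1.6
  r <- compute_hl_ratios(b, a)
  expect_equal(attr(r, "median_ratio"), 1.6)
  expect_equal(r$log2_ratio, rep(log2(1.6), 20))

  disjoint <- fits_frame(sprintf("Q%02d", 1:20), HL = seq(1, 20))
  expect_error(compute_hl_ratios(a, disjoint), "share no proteins")
})

test_that("proportion z-test matches its closed form", {
  # 50 of 100 above one: no evidence
  r <- c(rep(1.5, 50), rep(0.5, 50))
  z <- ratio_proportion_ztest(r)
  expect_equal(z$z, 0)
  expect_equal(z$p_value, 1)
  # 65 of 100: z = (0.65 - 0.5) / sqrt(0.25/100) = 3
  r <- c(rep(1.5, 65), rep(0.5, 35))
  z <- ratio_proportion_ztest(r)
  expect_equal(z$z, 3, tolerance = 1e-12)
  expect_equal(z$p_value, 2 * pnorm(-3), tolerance = 1e-12)
  # all 100 above: z = 10
  z <- ratio_proportion_ztest(rep(2, 100))
  expect_equal(z$z, 10, tolerance = 1e-12)
  expect_lt(z$p_value, 1e-15)
  # ties at exactly 1 are dropped; small n refused
  expect_error(ratio_proportion_ztest(c(rep(1, 95), rep(2, 5))), "at least 10")
})

test_that("slope difference test matches the Welch closed form", {
  a <- fits_frame("P1", HL = log(2) / 0.3, slope_se = 0.01, df = 11)
  b <- fits_frame("P1", HL = log(2) / 0.2, slope_se = 0.01, df = 11)
  ht <- hl_difference_test(a, b)
  expect_equal(ht$t, 0.1 / sqrt(2e-4), tolerance = 1e-12)  # ~7.07
  expect_equal(ht$df, 22, tolerance = 1e-9)
  expect_lt(ht$p_value, 1e-3)
  # equal rates: t = 0, p = 1
  ht0 <- hl_difference_test(a, a)
  expect_equal(ht0$t, 0)
  expect_equal(ht0$p_value, 1)
  # proteins missing on one side are skipped
  b2 <- fits_frame("P2", HL = 3)
  expect_equal(nrow(hl_difference_test(a, b2)), 0)
})

test_that("Benjamini-Hochberg step-up reproduces the worked example", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # independent step-up oracle: q_(i) = min_(j >= i) p_(j) * m / j
  set.seed(31)
  p <- runif(40)^2
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(p[o][i:m] * m / (i:m)))
  }, numeric(1))
  q <- bh_fdr(p)
  expect_equal(q[o], q_sorted, tolerance = 1e-12)
  expect_true(all(diff(q[o]) >= 0))
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential abundance finds no change between identical cohorts", {
  set.seed(32)
  obs <- lapply(1:4, function(s) {
    make_obs(c("ALLGKR"), f = 0, p = 0, A = 1e6,
             sample = sprintf("s%d", s), protein = "P1")
  })
  more <- lapply(1:4, function(s) {
    make_obs(c("GLKVVR"), f = 0, p = 0, A = 5e5,
             sample = sprintf("s%d", s), protein = "P2")
  })
  one_cohort <- do.call(make_obs_table, c(obs, more))
  da <- differential_abundance(one_cohort, one_cohort, min_mice = 3L)
  expect_equal(da$log2_fc, c(0, 0))
  expect_equal(da$p_value, c(1, 1), tolerance = 1e-9)
})

test_that("a global intensity rescaling is removed by normalization", {
  set.seed(33)
  rows <- list()
  for (s in 1:4) {
    for (pr in 1:6) {
      rows[[length(rows) + 1]] <- make_obs(
        sprintf("ALLGK%sR", paste(rep("A", pr), collapse = "")),
        f = 0, p = 0, A = 10^runif(1, 5, 7) * (1 + 0.05 * s),
        sample = sprintf("s%d", s), protein = sprintf("P%d", pr))
    }
  }
  obs <- do.call(make_obs_table, rows)
  doubled <- obs
  doubled$sample <- paste0(doubled$sample, "_b")
  doubled$intensities <- lapply(doubled$intensities, function(v) 2 * v)
  doubled$total_auc <- 2 * doubled$total_auc
  da <- differential_abundance(obs, doubled, min_mice = 3L)
  expect_true(all(abs(da$log2_fc) < 1e-9))
})

test_that("extreme half-life selection uses floor counts and id tie-breaks", {
  fits <- fits_frame(sprintf("P%02d", 1:10), HL = 10:1)
  expect_setequal(select_extreme_hl(fits, 0.2, "shortest"),
                  c("P09", "P10"))
  expect_setequal(select_extreme_hl(fits, 0.2, "longest"),
                  c("P01", "P02"))
  # all equal: deterministic id order
  tied <- fits_frame(sprintf("P%02d", 10:1), HL = 5)
  expect_identical(select_extreme_hl(tied, 0.3, "shortest"),
                   c("P01", "P02", "P03"))
  big <- fits_frame(sprintf("P%03d", 1:950), HL = runif(950, 1, 10))
  expect_length(select_extreme_hl(big, 0.2, "longest"), 190)
})

test_that("pathway summaries aggregate half-lives with a one-way ANOVA", {
  set.seed(34)
  mapping <- data.frame(protein = sprintf("P%02d", 1:20), pathway = "glycolysis")
  g1 <- fits_frame(sprintf("P%02d", 1:20), HL = rnorm(20, 3, 0.5))
  same <- pathway_summary(list(A = g1, B = g1), mapping)
  expect_gt(same$anova_p[1], 0.99)
  g2 <- g1; g2$HL <- rnorm(20, 6, 0.5)
  diff_groups <- pathway_summary(list(A = g1, B = g2), mapping)
  expect_lt(diff_groups$anova_p[1], 1e-6)
  expect_true(all(diff_groups$q1 <= diff_groups$median_HL))
  expect_true(all(diff_groups$median_HL <= diff_groups$q3))
  expect_true(all(diff_groups$p05 <= diff_groups$q1))
  expect_true(all(diff_groups$q3 <= diff_groups$p95))
  # unmeasured pathways are omitted with a message
  mapping2 <- rbind(mapping, data.frame(protein = "QQ", pathway = "absent"))
  expect_message(out <- pathway_summary(list(A = g1), mapping2), "omitted")
  expect_false("absent" %in% out$pathway)
})

test_that("comparison matrices keep proteins significant in any comparison", {
  one <- data.frame(protein = "P1", log2_ratio = 1.0, q_value = 0.01)
  m <- comparison_matrix(list(cmp1 = one))
  expect_equal(dim(m), c(1, 1))
  expect_equal(m["P1", "cmp1"], 1.0)
  none <- data.frame(protein = sprintf("P%d", 1:5),
                     log2_ratio = rnorm(5), q_value = 0.5)
  expect_equal(nrow(comparison_matrix(list(cmp1 = none))), 0)
  # three comparisons, union of significant proteins, NA where missing
  c1 <- data.frame(protein = c("P1", "P2"), log2_ratio = c(1, 2),
                   q_value = c(0.01, 0.2))
  c2 <- data.frame(protein = c("P2", "P3"), log2_ratio = c(2, 3),
                   q_value = c(0.03, 0.2))
  c3 <- data.frame(protein = "P4", log2_ratio = 4, q_value = 0.04)
  m3 <- comparison_matrix(list(a = c1, b = c2, c = c3))
  expect_equal(dim(m3), c(3, 3))
  expect_true(is.na(m3["P1", "b"]))
  expect_equal(m3["P2", "b"], 2)
})

test_that("Spearman comparison matches the rank formula and is monotone-invariant", {
  x <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  expect_equal(spearman_comparison(x, x)$rho, 1)
  expect_equal(spearman_comparison(x, -x)$rho, -1)
  # rho = 1 - 6*sum(d^2)/(n(n^2-1)): swapping the first two ranks of five
  # gives sum(d^2) = 2, so rho = 1 - 12/120 = 0.9
  swapped <- c(a = 2, b = 1, c = 3, d = 4, e = 5)
  expect_equal(spearman_comparison(x, swapped)$rho, 0.9)
  set.seed(35)
  y <- rnorm(5); names(y) <- names(x)
  base <- spearman_comparison(x, y)
  trans <- spearman_comparison(exp(x), y)
  expect_equal(base$rho, trans$rho)
  expect_equal(base$p_value, trans$p_value)
  const <- spearman_comparison(x, c(a = 1, b = 1, c = 1, d = 1, e = 1))
  expect_true(const$degenerate)
})
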