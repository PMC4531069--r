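make_pooled_input <- function(f, day, auc = rep(1, length(f)),
                              protein = "P1", unique = 1L,
                              peptide = sprintf("pep%d", seq_along(f))) {
  data.frame(peptide = peptide, protein = protein, unique = unique,
             sample = sprintf("s%d", seq_along(f)), cohort = "X",
             day = day, total_auc = auc, f = f, clipped = FALSE,
             stringsAsFactors = FALSE)
}

test_that("pooling is the AUC-weighted mean over unique peptides", {
  est <- data.frame(peptide = c("a", "b"), protein = "P1", unique = 1L,
                    sample = "s1", cohort = "X", day = 3,
                    total_auc = c(1, 3), f = c(0.2, 0.4), clipped = FALSE,
                    stringsAsFactors = FALSE)
  pooled <- pool_protein_fraction_new(est)
  expect_equal(pooled$f, 0.35)
  expect_equal(pooled$weight, 4)
  expect_identical(pooled$n_peptides, 2L)
  # a single peptide passes through unchanged
  one <- pool_protein_fraction_new(est[1, ])
  expect_equal(one$f, 0.2)
})

test_that("non-unique peptides are excluded from pooling", {
  est <- data.frame(peptide = letters[1:7], protein = "P1",
                    unique = c(1L, 1L, 1L, 1L, 1L, 0L, 0L),
                    sample = "s1", cohort = "X", day = 3,
                    total_auc = 1, f = c(rep(0.3, 5), 0.9, 0.9),
                    clipped = FALSE, stringsAsFactors = FALSE)
  pooled <- pool_protein_fraction_new(est)
  expect_identical(pooled$n_peptides, 5L)
  expect_equal(pooled$f, 0.3)
  # a protein with only shared peptides is dropped with a message
  est$unique <- 0L
  expect_message(out <- pool_protein_fraction_new(est), "dropped")
  expect_equal(nrow(out), 0)
})

test_that("splitting a peptide into half-weight duplicates leaves pooled f unchanged", {
  est <- data.frame(peptide = c("a", "b"), protein = "P1", unique = 1L,
                    sample = "s1", cohort = "X", day = 3,
                    total_auc = c(2, 6), f = c(0.2, 0.4), clipped = FALSE,
                    stringsAsFactors = FALSE)
  split_est <- rbind(est, est)
  split_est$peptide <- c("a1", "b1", "a2", "b2")
  split_est$total_auc <- split_est$total_auc / 2
  expect_equal(pool_protein_fraction_new(split_est)$f,
               pool_protein_fraction_new(est)$f)
})

test_that("noiseless first-order data is fit exactly", {
  k_true <- log(2) / 3.1
  day <- rep(c(3, 7, 12, 17), each = 3)
  tc <- data.frame(day = day, f = 1 - exp(-k_true * day))
  fit <- fit_first_order(tc)
  expect_lt(abs(fit$k - k_true) / k_true, 1e-9)
  expect_equal(fit$HL, 3.1, tolerance = 1e-9)
  expect_equal(fit$HL * fit$k, log(2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_false(fit$nonpositive_rate)
})

test_that("flat time courses give a zero rate and infinite half-life", {
  tc <- data.frame(day = c(3, 7, 12, 17), f = 0)
  fit <- fit_first_order(tc)
  expect_equal(fit$k, 0)
  expect_identical(fit$HL, Inf)
  expect_true(fit$nonpositive_rate)
})

test_that("half-life follows the first-order definition", {
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(half_life(0.2236), 3.1, tolerance = 1e-3)
  expect_equal(half_life(2 * log(2)), 0.5)
  expect_identical(half_life(0), Inf)
  expect_identical(half_life(-1), Inf)
})

test_that("near-saturated points are excluded and counted", {
  k_true <- log(2) / 1.0
  day <- rep(c(3, 7, 12, 17), each = 3)
  tc <- data.frame(day = day, f = 1 - exp(-k_true * day))
  # f(7) onward exceeds the default 0.97 saturation cutoff
  fit <- fit_first_order(tc, min_points = 3L)
  expect_identical(fit$n_points, 3L)
  expect_identical(fit$n_saturated, 9L)
  expect_lt(abs(fit$k - k_true) / k_true, 1e-9)
  expect_error(fit_first_order(tc, min_points = 4L), "usable points")
})

test_that("free-intercept fits recover offset time courses", {
  k_true <- 0.15
  day <- rep(c(3, 7, 12, 17), each = 3)
  y <- 0.2 + k_true * day
  tc <- data.frame(day = day, f = 1 - exp(-y))
  fit <- fit_first_order(tc, intercept = TRUE)
  expect_lt(abs(fit$k - k_true) / k_true, 1e-9)
})

test_that("turnover table fitting covers every protein and cohort", {
  set.seed(21)
  day <- rep(c(3, 7, 12, 17), each = 3)
  blocks <- list()
  for (pr in c("P1", "P2")) {
    for (co in c("A", "B")) {
      hl <- runif(1, 2, 8)
      blocks[[paste(pr, co)]] <- data.frame(
        protein = pr, cohort = co, sample = sprintf("%s_%d", co, 1:12),
        day = day, f = 1 - exp(-log(2) / hl * day), weight = 1,
        n_peptides = 1L, true_hl = hl, stringsAsFactors = FALSE)
    }
  }
  pooled <- do.call(rbind, blocks)
  fits <- fit_turnover(pooled)
  expect_equal(nrow(fits), 4)
  first <- !duplicated(paste(pooled$protein, pooled$cohort))
  truth <- stats::setNames(pooled$true_hl[first],
                           paste(pooled$protein, pooled$cohort)[first])
  expect_equal(fits$HL, unname(truth[paste(fits$protein, fits$cohort)]),
               tolerance = 1e-9)
  expect_true(all(abs(fits$HL * fits$k - log(2)) < 1e-12))
})

test_that("steady-state slopes are zero for constant abundance", {
  obs <- data.frame(peptide = "a", day = c(3, 7, 12, 17), total_auc = 5)
  ss <- steady_state_slopes(obs)
  expect_equal(ss$slopes$slope, 0)
})

test_that("a linear abundance drift is detected with the textbook slope", {
  obs <- data.frame(peptide = "a", day = c(3, 7, 12, 17),
                    total_auc = c(10, 12, 14, 16))
  ss <- steady_state_slopes(obs)
  # hand regression: S_ty / S_tt = 47 / 110.75
  expect_equal(ss$slopes$slope, 47 / 110.75, tolerance = 1e-12)
  expect_lt(ss$slopes$p_value, 0.01)
})

test_that("peptides at fewer than three timepoints are skipped", {
  obs <- data.frame(peptide = rep(c("a", "b"), c(4, 2)),
                    day = c(3, 7, 12, 17, 3, 7),
                    total_auc = c(5, 5, 5, 5, 1, 2))
  ss <- steady_state_slopes(obs)
  expect_identical(ss$slopes$peptide, "a")
})
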