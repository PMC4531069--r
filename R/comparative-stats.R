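# Between-group comparisons: half-life ratios, per-protein significance
# with FDR control, differential abundance, pathway aggregation and rank
# correlations between comparisons.

#' Pairwise half-life ratios between two groups
#'
#' Inner-joins two turnover tables on protein id and reports the per-protein
#' ratio `HL_A / HL_B` with its log2. Comparing the same protein across
#' groups removes the (very broad) between-protein half-life variation and
#' is far more sensitive than comparing the marginal distributions.
#'
#' @param fits_A,fits_B Turnover tables (from [fit_turnover()]) with
#'   finite `HL`; rows with non-finite `HL` are dropped.
#' @param labels Length-2 character vector naming the groups.
#' @return Data.frame `protein`, `HL_A`, `HL_B`, `ratio`, `log2_ratio`
#'   with attributes `labels` and `median_ratio`.
#' @export
compute_hl_ratios <- function(fits_A, fits_B, labels = c("A", "B")) {
  a <- fits_A[is.finite(fits_A$HL), c("protein", "HL")]
  b <- fits_B[is.finite(fits_B$HL), c("protein", "HL")]
  m <- merge(a, b, by = "protein", suffixes = c("_A", "_B"))
  if (nrow(m) == 0) stop("groups share no proteins with finite half-lives")
  m$ratio <- m$HL_A / m$HL_B
  m$log2_ratio <- log2(m$ratio)
  attr(m, "labels") <- labels
  attr(m, "median_ratio") <- stats::median(m$ratio)
  m
}

#' z-test on the proportion of half-life ratios above one
#'
#' Under no group effect each protein's ratio is equally likely to fall on
#' either side of 1, so the proportion above 1 is Binomial(n, 1/2). Tests
#' that proportion against 0.5 with the normal approximation
#' `z = (phat - 0.5) / sqrt(0.25 / n)`; ties at exactly 1 are dropped.
#' A one-sample t-test on the log2 ratios is returned alongside as a
#' cross-check reading of the same question.
#'
#' @param ratios Ratio table from [compute_hl_ratios()] (or a numeric
#'   vector of ratios).
#' @return List with `proportion_above_1`, `n`, `z`, `p_value`, and
#'   `t_test_log2` (an `htest` on the log2 ratios).
#' @export
ratio_proportion_ztest <- function(ratios) {
  r <- if (is.data.frame(ratios)) ratios$ratio else ratios
  r <- r[r != 1]
  n <- length(r)
  if (n < 10) stop("need at least 10 untied ratios for the normal approximation")
  phat <- mean(r > 1)
  z <- (phat - 0.5) / sqrt(0.25 / n)
  list(proportion_above_1 = phat, n = n, z = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       t_test_log2 = tryCatch(stats::t.test(log2(r), mu = 0),
                              error = function(e) NULL))
}

#' Per-protein half-life difference test between two groups
#'
#' Welch-style t-test on the difference of the two first-order rate
#' constants, using each regression's slope standard error and a
#' Satterthwaite degrees-of-freedom approximation. q-values are
#' Benjamini-Hochberg over all tested proteins.
#'
#' @param fits_A,fits_B Turnover tables with `k`, `slope_se`, `df`.
#' @return Data.frame `protein`, `k_A`, `k_B`, `t`, `df`, `p_value`,
#'   `q_value`; proteins missing from either side are skipped.
#' @export
hl_difference_test <- function(fits_A, fits_B) {
  cols <- c("protein", "k", "slope_se", "df")
  m <- merge(fits_A[fits_A$slope_se > 0, cols],
             fits_B[fits_B$slope_se > 0, cols],
             by = "protein", suffixes = c("_A", "_B"))
  v <- m$slope_se_A^2 + m$slope_se_B^2
  tstat <- (m$k_A - m$k_B) / sqrt(v)
  df <- v^2 / (m$slope_se_A^4 / m$df_A + m$slope_se_B^4 / m$df_B)
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(protein = m$protein, k_A = m$k_A, k_B = m$k_B,
             t = tstat, df = df, p_value = p, q_value = bh_fdr(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, capped at
#' one and order-preserving (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential protein abundance between two cohorts
#'
#' Per mouse, protein abundance is the summed total AUC (labeled plus
#' unlabeled chromatographic peak area) over the protein's unique
#' peptides. Sample depth is normalized with median-of-ratios size
#' factors computed jointly over both cohorts (the median ratio to each
#' protein's across-sample geometric mean, which is insensitive to a
#' minority of truly changing proteins), then abundances are log2
#' transformed, compared with a two-sided Welch t-test per protein, and
#' FDR-adjusted. The steady-state design means mice from all labeling
#' days can be used together.
#'
#' @param observations_A,observations_B Peptide observation tables for the
#'   two cohorts (`protein`, `unique`, `sample`, `total_auc`).
#' @param min_mice Minimum mice per group with nonzero abundance.
#' @return Data.frame `protein`, `log2_fc` (A over B, group means of
#'   normalized log2 abundance), `p_value`, `q_value`, `n_A`, `n_B`.
#' @export
differential_abundance <- function(observations_A, observations_B,
                                   min_mice = 3L) {
  ab_A <- .protein_abundance_matrix(observations_A)
  ab_B <- .protein_abundance_matrix(observations_B)
  shared <- intersect(rownames(ab_A), rownames(ab_B))
  raw <- cbind(ab_A[shared, , drop = FALSE], ab_B[shared, , drop = FALSE])
  idx_A <- seq_len(ncol(ab_A))
  # two-pass normalization: size factors from the median of ratios are
  # pulled toward truly changing proteins when the changes are one-sided,
  # so a first round of tests identifies apparent changers and the final
  # size factors are computed on the stable remainder
  joint <- log2(.median_of_ratios_normalize(raw))
  first <- .abundance_tests(joint, idx_A, min_mice)
  stable <- first$protein[first$q_value > 0.5]
  if (length(stable) >= 50) {
    joint <- log2(.median_of_ratios_normalize(raw, reference = stable))
  }
  out <- .abundance_tests(joint, idx_A, min_mice)
  n_skipped <- length(shared) - nrow(out)
  if (n_skipped > 0) {
    message(n_skipped, " protein(s) skipped in abundance comparison ",
            "(too few mice with signal)")
  }
  out
}

.abundance_tests <- function(joint, idx_A, min_mice) {
  rows <- lapply(rownames(joint), function(pr) {
    xa <- joint[pr, idx_A]; xb <- joint[pr, -idx_A]
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    if (length(xa) < min_mice || length(xb) < min_mice) return(NULL)
    # degenerate zero-variance groups: identical means are a perfect null,
    # different means a perfect separation
    p <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    } else stats::t.test(xa, xb)$p.value
    data.frame(protein = pr, log2_fc = mean(xa) - mean(xb),
               p_value = p, n_A = length(xa), n_B = length(xb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out$q_value <- bh_fdr(out$p_value)
  out
}

# proteins x samples matrix of summed unique-peptide AUC (raw scale);
# zero-abundance cells are treated as missing downstream.
.protein_abundance_matrix <- function(observations) {
  obs <- observations[observations$unique == 1L, , drop = FALSE]
  mat <- tapply(obs$total_auc, list(factor(obs$protein), factor(obs$sample)),
                sum)
  mat[is.na(mat)] <- 0
  mat
}

# median-of-ratios size-factor normalization: reference is each protein's
# geometric mean over samples with signal; a sample's size factor is its
# median ratio to the reference, so it tracks the unchanged majority of
# proteins rather than the overall intensity distribution. `reference`
# optionally restricts the median to a set of stable proteins.
.median_of_ratios_normalize <- function(mat, reference = rownames(mat)) {
  logm <- log(mat)
  logm[!is.finite(logm)] <- NA
  ref <- rowMeans(logm, na.rm = TRUE)
  use <- rownames(mat) %in% reference
  sf <- apply((logm - ref)[use, , drop = FALSE], 2, stats::median,
              na.rm = TRUE)
  sweep(mat, 2, exp(sf), "/")
}

#' Select the shortest- or longest-lived fraction of proteins
#'
#' @param fits Turnover table with finite `HL`.
#' @param fraction Fraction of proteins to select (0 < fraction < 1);
#'   `floor(fraction * n)` proteins are returned.
#' @param end `"shortest"` or `"longest"`.
#' @return Character vector of protein ids; ties in `HL` are broken by
#'   protein id so the selection is deterministic.
#' @export
select_extreme_hl <- function(fits, fraction, end = c("shortest", "longest")) {
  end <- match.arg(end)
  stopifnot(fraction > 0, fraction < 1)
  f <- fits[is.finite(fits$HL), ]
  k <- floor(fraction * nrow(f))
  ord <- order(if (end == "shortest") f$HL else -f$HL, f$protein)
  f$protein[ord][seq_len(k)]
}

#' Half-life summaries per pathway or compartment
#'
#' For each pathway in the mapping, summarizes the member proteins'
#' half-lives per group (median, mean, quartiles, 5th/95th percentiles)
#' and tests for a group effect with a one-way ANOVA of HL across groups
#' within the pathway.
#'
#' @param fits_by_group Named list of turnover tables, one per group.
#' @param mapping Data.frame `protein`, `pathway` (optionally `category`).
#' @return Data.frame with one row per pathway x group plus the pathway's
#'   ANOVA p-value (repeated across its rows); pathways with no measured
#'   proteins are omitted with a message.
#' @export
pathway_summary <- function(fits_by_group, mapping) {
  stopifnot(!is.null(names(fits_by_group)))
  out <- list()
  skipped <- character()
  for (pw in unique(mapping$pathway)) {
    members <- mapping$protein[mapping$pathway == pw]
    hls <- lapply(fits_by_group, function(f) {
      f$HL[f$protein %in% members & is.finite(f$HL)]
    })
    hls <- hls[vapply(hls, length, integer(1)) > 0]
    if (length(hls) == 0) { skipped <- c(skipped, pw); next }
    p_anova <- if (length(hls) >= 2) {
      vals <- unlist(hls, use.names = FALSE)
      grp <- factor(rep(names(hls), vapply(hls, length, integer(1))))
      summary(stats::aov(vals ~ grp))[[1]][["Pr(>F)"]][1]
    } else NA_real_
    for (g in names(hls)) {
      q <- stats::quantile(hls[[g]], c(0.05, 0.25, 0.5, 0.75, 0.95),
                           names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        pathway = pw, group = g, n = length(hls[[g]]),
        mean_HL = mean(hls[[g]]), p05 = q[1], q1 = q[2], median_HL = q[3],
        q3 = q[4], p95 = q[5], anova_p = p_anova,
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped) > 0) {
    message(length(skipped), " pathway(s) with no measured proteins omitted: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Log2-ratio matrix across comparisons for heatmap export
#'
#' Builds a proteins x comparisons matrix of log2 ratios restricted to
#' proteins significant (q below the threshold) in at least one
#' comparison; cells absent from a comparison are `NA`.
#'
#' @param comparisons Named list; each element a data.frame with columns
#'   `protein`, `log2_ratio` (or `log2_fc`) and `q_value`.
#' @param q_threshold Significance threshold for inclusion (default 0.05).
#' @return Numeric matrix, rownames protein ids, colnames comparison
#'   names; zero rows when nothing passes the threshold.
#' @export
comparison_matrix <- function(comparisons, q_threshold = 0.05) {
  stopifnot(!is.null(names(comparisons)))
  get_lr <- function(d) if ("log2_ratio" %in% names(d)) d$log2_ratio else d$log2_fc
  selected <- sort(unique(unlist(lapply(comparisons, function(d) {
    d$protein[!is.na(d$q_value) & d$q_value < q_threshold]
  }))))
  mat <- matrix(NA_real_, nrow = length(selected), ncol = length(comparisons),
                dimnames = list(selected, names(comparisons)))
  for (nm in names(comparisons)) {
    d <- comparisons[[nm]]
    hit <- d$protein %in% selected
    mat[d$protein[hit], nm] <- get_lr(d)[hit]
  }
  mat
}

#' Spearman correlation between two comparisons' log-ratios
#'
#' Rank correlation (average ranks for ties) with a two-sided p-value from
#' the t approximation, pairing proteins shared by the two vectors.
#'
#' @param x,y Named numeric vectors of log ratios (names are protein ids),
#'   or unnamed vectors of equal length already paired.
#' @return List `rho`, `p_value`, `n`, and `degenerate` flag (`TRUE` when
#'   either vector is constant, in which case `rho` is `NA`).
#' @export
spearman_comparison <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
  }
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided",
                    exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       degenerate = FALSE)
}
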