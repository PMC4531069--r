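# First-order turnover kinetics: pool peptide-level fraction-new into
# protein time courses and fit k from -ln(1 - f) vs t.

#' Pool peptide fraction-new into protein time courses
#'
#' Discards peptides that do not map uniquely to a single protein, then,
#' per protein and mouse, forms the AUC-weighted mean fraction-new over
#' the protein's unique peptides. One pooled point per mouse.
#'
#' @param estimates Per-peptide table from [percent_new_per_peptide()]
#'   (columns `protein`, `cohort`, `sample`, `day`, `unique`, `total_auc`,
#'   `f`; rows with `NA` `f` are ignored).
#' @param use_clipped Keep points whose mixture fit was clipped to the
#'   \[0, 1\] boundary (default `TRUE`: clipping preserves sample size).
#' @return A data.frame with one row per protein x cohort x sample:
#'   `protein`, `cohort`, `sample`, `day`, `f` (pooled), `weight` (summed
#'   AUC), `n_peptides`.
#' @export
pool_protein_fraction_new <- function(estimates, use_clipped = TRUE) {
  keep <- estimates$unique == 1L & !is.na(estimates$f)
  if (!use_clipped) keep <- keep & !estimates$clipped
  dropped <- setdiff(unique(estimates$protein), unique(estimates$protein[keep]))
  if (length(dropped) > 0) {
    message(length(dropped), " protein(s) without unique peptides dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  est <- estimates[keep, , drop = FALSE]
  key <- interaction(est$protein, est$cohort, est$sample, drop = TRUE)
  w_sum <- tapply(est$total_auc, key, sum)
  fw_sum <- tapply(est$total_auc * est$f, key, sum)
  first <- !duplicated(key)
  out <- data.frame(
    protein = est$protein[first],
    cohort = est$cohort[first],
    sample = est$sample[first],
    day = est$day[first],
    stringsAsFactors = FALSE
  )
  k <- as.character(key[first])
  out$f <- as.numeric(fw_sum[k] / w_sum[k])
  out$weight <- as.numeric(w_sum[k])
  out$n_peptides <- as.integer(table(key)[k])
  if ("f_var_rel" %in% names(est)) {
    # variance of the AUC-weighted mean, on the same relative scale as the
    # per-peptide values; missing values take the group median
    v <- est$f_var_rel
    med <- tapply(v, key, function(x) stats::median(x, na.rm = TRUE))
    v[is.na(v)] <- as.numeric(med[as.character(key)])[is.na(v)]
    vw_sum <- tapply(est$total_auc^2 * v, key, sum)
    out$f_var_rel <- as.numeric(vw_sum[k]) / out$weight^2
  }
  out[order(out$protein, out$cohort, out$day, out$sample), , drop = FALSE]
}

#' Fit first-order label-appearance kinetics for one protein
#'
#' With protein pools at steady state, the fraction new follows
#' `f(t) = 1 - exp(-k t)`, so `-ln(1 - f)` is linear in time through the
#' origin. The rate constant is the zero-intercept least-squares slope
#' (a free intercept is available via `intercept = TRUE`); the half-life
#' is `ln(2) / k`. Points with `f` within `1e-6` of 1 are excluded from
#' the log transform and counted in `n_saturated`.
#'
#' @param time_course Data.frame with columns `day` and `f` (one row per
#'   mouse), e.g. one protein/cohort block of
#'   [pool_protein_fraction_new()] output.
#' @param min_points Minimum usable points; fewer refuses the fit.
#' @param intercept Fit a free intercept instead of forcing f(0) = 0.
#' @param f_max Saturation cutoff: points with `f` above it are excluded
#'   from the log transform and counted in `n_saturated`. Near-saturated
#'   points sit within measurement noise of the `f = 1` boundary, so their
#'   transformed residuals are truncated and strongly skewed rather than
#'   informative; at the default 0.97 a four-timepoint design at 3-17
#'   days can resolve half-lives down to roughly 1.4 days.
#' @param weighting `"delta"` (default) iteratively reweights points by
#'   `(1 - f)^2 = exp(-2 k t)`, the delta-method variance stabilizer for
#'   the log transform: measurement noise on `f` is roughly constant, so
#'   the transformed residual variance grows as `1 / (1 - f)^2` and
#'   unweighted least squares lets the noisiest late points dominate and
#'   understates the slope standard error. `"none"` gives plain OLS.
#' @return List with `k` (per day), `HL` (days; `Inf` when `k <= 0`),
#'   `slope_se`, `r_squared` (on the transformed, weighted scale),
#'   `n_points`, `n_saturated`, and `nonpositive_rate` flag.
#' @export
fit_first_order <- function(time_course, min_points = 4L, intercept = FALSE,
                            weighting = c("delta", "none"), f_max = 0.97) {
  weighting <- match.arg(weighting)
  ok <- !is.na(time_course$f) & time_course$f >= 0 &
    time_course$f <= f_max & time_course$day > 0
  n_sat <- sum(!is.na(time_course$f) & time_course$f > f_max)
  t <- time_course$day[ok]
  y <- -log(1 - time_course$f[ok])
  n <- length(y)
  if (n < min_points) {
    stop("only ", n, " usable points (min_points = ", min_points, ")")
  }
  # relative per-point variance of f (from the deconvolution's precision
  # estimates, when available); missing or absent values fall back to the
  # constant-variance assumption
  v <- if (weighting == "delta" && "f_var_rel" %in% names(time_course)) {
    time_course$f_var_rel[ok]
  } else rep(1, n)
  good <- is.finite(v) & v > 0
  if (!any(good)) v[] <- 1 else v[!good] <- stats::median(v[good])
  w <- if (weighting == "delta") 1 / v else rep(1, n)
  n_par <- if (intercept) 2L else 1L
  n_iter <- if (weighting == "delta") 3L else 1L
  for (it in seq_len(n_iter)) {
    if (intercept) {
      fit <- stats::lm.wfit(cbind(1, t), y, w)
      k <- unname(fit$coefficients[2])
      res <- fit$residuals
      tm <- sum(w * t) / sum(w)
      denom <- sum(w * (t - tm)^2)
      tss <- sum(w * (y - sum(w * y) / sum(w))^2)
    } else {
      denom <- sum(w * t * t)
      k <- sum(w * t * y) / denom
      res <- y - k * t
      tss <- sum(w * y * y)  # zero-intercept convention
    }
    if (it < n_iter) {
      # next-iteration weights from the current rate estimate; a
      # non-positive slope gives no signal to weight by
      if (k <= 0) break
      w <- exp(-2 * pmin(k * t, 350)) / v
    }
  }
  # with 1/variance weights this is homoscedastic OLS in the transformed
  # coordinates, so the usual residual degrees of freedom apply
  df <- n - n_par
  rss <- sum(w * res^2)
  se <- sqrt(rss / df / denom)
  list(k = k,
       HL = half_life(k),
       slope_se = se,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       n_points = n,
       df = df,
       n_saturated = n_sat,
       nonpositive_rate = k <= 0)
}

#' Half-life from a first-order rate constant
#'
#' @param k Rate constant (per day).
#' @return `ln(2) / k` in days; `Inf` for `k <= 0`.
#' @export
half_life <- function(k) {
  ifelse(k > 0, log(2) / k, Inf)
}

#' Fit turnover for every protein x cohort in a pooled table
#'
#' @param pooled Output of [pool_protein_fraction_new()].
#' @inheritParams fit_first_order
#' @return Data.frame with one row per protein x cohort with the
#'   [fit_first_order()] fields; proteins with too few points are omitted
#'   with a message.
#' @export
fit_turnover <- function(pooled, min_points = 4L, intercept = FALSE,
                         weighting = c("delta", "none"), f_max = 0.97) {
  weighting <- match.arg(weighting)
  blocks <- split(pooled, list(pooled$protein, pooled$cohort), drop = TRUE)
  rows <- lapply(blocks, function(b) {
    fit <- tryCatch(fit_first_order(b, min_points, intercept, weighting,
                                    f_max),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(protein = b$protein[1], cohort = b$cohort[1],
               k = fit$k, HL = fit$HL, slope_se = fit$slope_se,
               r_squared = fit$r_squared, n_points = fit$n_points,
               df = fit$df, n_saturated = fit$n_saturated,
               nonpositive_rate = fit$nonpositive_rate,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    message(skipped, " protein/cohort fit(s) skipped (too few usable points)")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Steady-state check: peptide abundance vs time
#'
#' At steady state synthesis balances degradation and total peptide
#' abundance is time-invariant, so per-peptide regressions of total AUC on
#' labeling day should have slopes centered at zero. Returns per-peptide
#' slopes with p-values and a one-sample t-test of the slope distribution
#' against zero.
#'
#' @param observations Peptide observation table with `peptide`, `day`,
#'   `total_auc` (peptides observed at fewer than 3 distinct timepoints
#'   are skipped).
#' @return List with `slopes` (data.frame: `peptide`, `slope`, `se`,
#'   `p_value`, `n`) and `center_test` (the `htest` for mean slope = 0).
#' @export
steady_state_slopes <- function(observations) {
  blocks <- split(observations, observations$peptide)
  rows <- lapply(blocks, function(b) {
    if (length(unique(b$day)) < 3L) return(NULL)
    t <- b$day; y <- b$total_auc; n <- length(y)
    tc <- t - mean(t)
    slope <- sum(tc * y) / sum(tc^2)
    res <- y - mean(y) - slope * tc
    se <- sqrt(sum(res^2) / (n - 2L) / sum(tc^2))
    tstat <- slope / se
    data.frame(peptide = b$peptide[1], slope = slope, se = se,
               p_value = 2 * stats::pt(-abs(tstat), n - 2L), n = n,
               stringsAsFactors = FALSE)
  })
  slopes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(slopes) <- NULL
  center <- if (nrow(slopes) >= 2 && stats::sd(slopes$slope) > 0) {
    stats::t.test(slopes$slope, mu = 0)
  } else {
    list(estimate = mean(slopes$slope), p.value = NA_real_,
         conf.int = c(NA_real_, NA_real_))
  }
  list(slopes = slopes, center_test = center)
}
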