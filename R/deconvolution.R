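# Two-component mixture deconvolution of observed isotopologue intensity
# vectors: old (fully unlabeled) protein follows the natural envelope, new
# protein follows the labeled envelope at the precursor-pool enrichment p.
# Label recycling is absorbed into p.

# Non-negative least squares for y ~ a*x1 + b*x2 with a, b >= 0. Two
# variables, so the active-set solution is closed form. Returns a, b, rss
# and whether the unconstrained optimum was clipped.
.nnls2 <- function(y, x1, x2) {
  g11 <- sum(x1 * x1); g22 <- sum(x2 * x2); g12 <- sum(x1 * x2)
  c1 <- sum(x1 * y); c2 <- sum(x2 * y); yty <- sum(y * y)
  det <- g11 * g22 - g12 * g12
  clipped <- FALSE
  if (det > 1e-14 * g11 * g22) {
    a <- (g22 * c1 - g12 * c2) / det
    b <- (g11 * c2 - g12 * c1) / det
  } else {
    # envelopes (numerically) collinear: attribute all signal to the old
    # component; f is unidentifiable at p ~ 0
    a <- c1 / g11; b <- 0
    clipped <- NA
  }
  if (!is.na(clipped) && (a < 0 || b < 0)) {
    clipped <- TRUE
    a1 <- max(c1 / g11, 0); r1 <- yty - 2 * a1 * c1 + a1^2 * g11
    b1 <- max(c2 / g22, 0); r2 <- yty - 2 * b1 * c2 + b1^2 * g22
    if (r1 <= r2) { a <- a1; b <- 0 } else { a <- 0; b <- b1 }
  }
  rss <- yty - 2 * (a * c1 + b * c2) +
    a^2 * g11 + 2 * a * b * g12 + b^2 * g22
  list(a = a, b = b, rss = max(rss, 0), clipped = isTRUE(clipped))
}

# rss(p) profiled over (a, b) for a grid of enrichment values, vectorized:
# S is the shift matrix of the peptide's natural envelope.
.rss_p_grid <- function(y, nat, S, L, p_grid) {
  W <- t(vapply(p_grid, function(p) stats::dbinom(0:L, L, p),
                numeric(L + 1L)))
  E <- W %*% S
  E <- E / rowSums(E)
  g11 <- sum(nat * nat)
  g22 <- rowSums(E * E)
  g12 <- drop(E %*% nat)
  c1 <- sum(nat * y)
  c2 <- drop(E %*% y)
  yty <- sum(y * y)
  det <- g11 * g22 - g12^2
  a <- (g22 * c1 - g12 * c2) / det
  b <- (g11 * c2 - g12 * c1) / det
  sing <- det <= 1e-14 * g11 * g22
  neg <- !sing & (a < 0 | b < 0)
  if (any(neg | sing)) {
    a1 <- pmax(c1 / g11, 0); r1 <- yty - 2 * a1 * c1 + a1^2 * g11
    b1 <- pmax(c2 / g22, 0); r2 <- yty - 2 * b1 * c2 + b1^2 * g22
    use1 <- r1 <= r2 | sing
    a[neg | sing] <- ifelse(use1, a1, 0)[neg | sing]
    b[neg | sing] <- ifelse(use1, 0, b1)[neg | sing]
  }
  yty - 2 * (a * c1 + b * c2) + a^2 * g11 + 2 * a * b * g12 + b^2 * g22
}

#' Fit the old/new isotopologue mixture to one observation
#'
#' Minimizes `|| y - A * ((1 - f) * natural + f * labeled(p)) ||^2` over
#' the fraction-new `f` in \[0, 1\], total abundance `A > 0` and, when
#' `p_fixed` is `NULL`, the precursor-pool enrichment `p` in \[0, 1\].
#' The inner problem is a two-variable non-negative least squares in
#' `(A(1-f), A f)`; the outer search over free `p` is a deterministic
#' coarse grid followed by golden-section refinement.
#'
#' @param intensities Observed isotopologue intensity vector, offset 0
#'   first; must be non-negative with a positive sum.
#' @param sequence Peptide sequence (used for composition and leucine
#'   count); must contain at least one leucine.
#' @param p_fixed Optional enrichment to hold fixed; when `NULL`, `p` is
#'   fitted jointly (requires two or more leucines for identifiability).
#' @param grid_points Number of coarse grid points on \[0, 1\] for the free
#'   `p` search.
#' @param tol Golden-section convergence tolerance on `p`.
#' @return List with `f`, `p`, `A`, `residual` (root-mean-square), and
#'   logical `clipped` (the unconstrained optimum lay outside `f` in
#'   \[0, 1\]).
#' @export
fit_mixture <- function(intensities, sequence, p_fixed = NULL,
                        grid_points = 101L, tol = 1e-9) {
  L <- count_label_sites(sequence)
  if (L == 0L) stop("peptide carries no label sites (no leucine)")
  if (any(intensities < 0)) stop("negative intensities")
  if (sum(intensities) <= 0) stop("all-zero intensity vector")
  max_offset <- 3L * L + 6L
  nat <- natural_envelope(composition_from_sequence(sequence), max_offset)
  y <- numeric(max_offset + 1L)
  m <- min(length(intensities), max_offset + 1L)
  y[seq_len(m)] <- intensities[seq_len(m)]
  .fit_mixture_core(y, nat, L, p_fixed, grid_points, tol)
}

.fit_mixture_core <- function(y, nat, L, p_fixed, grid_points = 101L,
                              tol = 1e-9, S = NULL) {
  if (is.null(S)) S <- shift_matrix(nat, L)
  if (!is.null(p_fixed)) {
    stopifnot(p_fixed >= 0, p_fixed <= 1)
    p_hat <- p_fixed
  } else {
    p_grid <- seq(0, 1, length.out = grid_points)
    rss <- .rss_p_grid(y, nat, S, L, p_grid)
    # deterministic tie-break toward the smallest enrichment: a fully
    # unlabeled observation fits every p equally well (up to float
    # cancellation noise) and is reported as p = 0, not an arbitrary grid
    # point; eps tracks the cancellation scale of the rss computation
    eps <- 64 * .Machine$double.eps * sum(y * y)
    i <- which(rss <= min(rss) + eps)[1]
    lo <- p_grid[max(i - 1L, 1L)]
    hi <- p_grid[min(i + 1L, length(p_grid))]
    if (max(rss[max(i - 1L, 1L):min(i + 1L, length(p_grid))]) <=
          min(rss) + eps && i == 1L) {
      p_hat <- p_grid[i]
    } else {
      f_obj <- function(p) .rss_p_grid(y, nat, S, L, p)
      p_hat <- .golden_min(f_obj, lo, hi, tol)
    }
  }
  lab <- drop(stats::dbinom(0:L, L, p_hat) %*% S)
  lab <- lab / sum(lab)
  sol <- .nnls2(y, nat, lab)
  A <- sol$a + sol$b
  f <- if (A > 0) sol$b / A else 0
  list(f = f, p = p_hat, A = A,
       residual = sqrt(sol$rss / length(y)), clipped = sol$clipped,
       f_var_rel = .f_var_rel(nat, lab, sol$a, sol$b))
}

# Delta-method variance of f = b / (a + b) under multiplicative intensity
# noise Var(y_i) = c * mu_i^2, up to the unknown common noise scale c:
# sandwich (X'X)^-1 X' diag(mu^2) X (X'X)^-1 contracted with grad f.
# These relative variances serve as precision weights downstream (pooling
# across peptides, kinetic regression), where only ratios matter.
.f_var_rel <- function(x1, x2, a, b) {
  A <- a + b
  if (A <= 0) return(NA_real_)
  mu <- a * x1 + b * x2
  g11 <- sum(x1 * x1); g12 <- sum(x1 * x2); g22 <- sum(x2 * x2)
  det <- g11 * g22 - g12 * g12
  if (det <= 1e-14 * g11 * g22) return(NA_real_)
  m2 <- mu * mu
  m11 <- sum(m2 * x1 * x1); m12 <- sum(m2 * x1 * x2); m22 <- sum(m2 * x2 * x2)
  # C = (X'X)^-1, S = C M C, var = g' S g with g = c(-b, a) / A^2
  c11 <- g22 / det; c12 <- -g12 / det; c22 <- g11 / det
  s11 <- c11 * (m11 * c11 + m12 * c12) + c12 * (m12 * c11 + m22 * c12)
  s12 <- c11 * (m11 * c12 + m12 * c22) + c12 * (m12 * c12 + m22 * c22)
  s22 <- c12 * (m11 * c12 + m12 * c22) + c22 * (m12 * c12 + m22 * c22)
  g1 <- -b / A^2; g2 <- a / A^2
  max(g1 * (s11 * g1 + s12 * g2) + g2 * (s12 * g1 + s22 * g2), 0)
}

.golden_min <- function(f, lo, hi, tol) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- f(x2)
    }
  }
  (lo + hi) / 2
}

#' Estimate per-sample precursor-pool enrichment
#'
#' Fits the mixture jointly in `(f, p)` for every peptide with at least two
#' leucines and takes the median of the per-peptide enrichments as the
#' sample value. Single-leucine peptides are excluded: for L = 1 only the
#' product `f * p` is identifiable, so they carry no information about `p`
#' on their own.
#'
#' @param observations Peptide observation table for one sample, as
#'   returned by [read_peptide_table()] or [simulate_cohort()] (columns
#'   `peptide`, `n_leucines`, `total_auc`, list-column `intensities`).
#' @param signal_floor Minimum `total_auc` for a peptide to be used
#'   (default 0: no intensity filter).
#' @param n_max Largest number of peptides used; when more qualify, the
#'   `n_max` highest-signal peptides are taken (the median is insensitive
#'   to the remainder and the cap keeps large cohorts fast).
#' @return List with `sample`, `p` (median enrichment), `n_peptides_used`,
#'   and `dispersion` (median absolute deviation of per-peptide `p`).
#' @export
estimate_sample_enrichment <- function(observations, signal_floor = 0,
                                       n_max = 200L) {
  keep <- observations$n_leucines >= 2L & observations$total_auc > signal_floor
  if (!any(keep)) {
    stop("no usable peptides with >= 2 leucines; supply the enrichment ",
         "externally via p_fixed")
  }
  obs <- observations[keep, , drop = FALSE]
  if (nrow(obs) > n_max) {
    obs <- obs[order(-obs$total_auc)[seq_len(n_max)], , drop = FALSE]
  }
  cache <- envelope_cache()
  p_vals <- vapply(seq_len(nrow(obs)), function(i) {
    pre <- cache(obs$peptide[i])
    y <- .pad_intensities(obs$intensities[[i]], length(pre$nat))
    .fit_mixture_core(y, pre$nat, pre$L, p_fixed = NULL, S = pre$S)$p
  }, numeric(1))
  list(sample = if ("sample" %in% names(obs)) obs$sample[1] else NA_character_,
       p = stats::median(p_vals),
       n_peptides_used = length(p_vals),
       dispersion = stats::mad(p_vals))
}

.pad_intensities <- function(v, len) {
  y <- numeric(len)
  m <- min(length(v), len)
  y[seq_len(m)] <- v[seq_len(m)]
  y
}

# Memoized per-sequence natural envelope, leucine count and shift matrix,
# keyed by peptide sequence. The store is package-global (envelopes depend
# only on the sequence and the shipped residue/isotope tables) so repeated
# pipeline stages and samples share the convolution work.
envelope_cache <- function() {
  if (is.null(.pt_env$envelopes)) {
    .pt_env$envelopes <- new.env(parent = emptyenv())
  }
  store <- .pt_env$envelopes
  function(sequence) {
    got <- store[[sequence]]
    if (!is.null(got)) return(got)
    L <- count_label_sites(sequence)
    nat <- natural_envelope(composition_from_sequence(sequence), 3L * L + 6L)
    val <- list(nat = nat, L = L,
                S = if (L > 0) shift_matrix(nat, L) else NULL)
    store[[sequence]] <- val
    val
  }
}

#' Fraction newly synthesized per peptide at a fixed sample enrichment
#'
#' Runs [fit_mixture()] with `p` held at the sample-level enrichment
#' estimate, returning one row per observation. An enrichment of zero (a
#' pre-label control sample) makes `f` unidentifiable and it is reported
#' as 0 with the `low_signal` flag unset and `clipped` `NA`-free.
#'
#' @param observations Peptide observation table (any number of samples;
#'   rows are fitted independently).
#' @param enrichment Either a single enrichment value or the list returned
#'   by [estimate_sample_enrichment()].
#' @param signal_floor Minimum `total_auc`; rows below it are flagged
#'   `low_signal` and skipped (`f = NA`).
#' @return The input table (minus the intensity list-column) with columns
#'   `f`, `p`, `fitted_A`, `residual`, `clipped`, `low_signal` appended.
#' @export
percent_new_per_peptide <- function(observations, enrichment,
                                    signal_floor = 0) {
  p <- if (is.list(enrichment)) enrichment$p else enrichment
  stopifnot(p >= 0, p <= 1)
  n <- nrow(observations)
  f <- rep(NA_real_, n); A <- rep(NA_real_, n); resid <- rep(NA_real_, n)
  fvar <- rep(NA_real_, n)
  clipped <- logical(n); low <- logical(n)
  cache <- envelope_cache()
  for (i in seq_len(n)) {
    if (observations$n_leucines[i] < 1L) { low[i] <- TRUE; next }
    if (observations$total_auc[i] <= signal_floor) { low[i] <- TRUE; next }
    if (p == 0) { f[i] <- 0; A[i] <- observations$total_auc[i]; next }
    pre <- cache(observations$peptide[i])
    y <- .pad_intensities(observations$intensities[[i]], length(pre$nat))
    fit <- .fit_mixture_core(y, pre$nat, pre$L, p_fixed = p, S = pre$S)
    f[i] <- fit$f; A[i] <- fit$A; resid[i] <- fit$residual
    fvar[i] <- fit$f_var_rel
    clipped[i] <- fit$clipped
  }
  out <- observations[setdiff(names(observations), "intensities")]
  out$f <- f
  out$p <- p
  out$fitted_A <- A
  out$residual <- resid
  out$f_var_rel <- fvar
  out$clipped <- clipped
  out$low_signal <- low
  out
}
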