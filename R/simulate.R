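# Synthetic study generator: peptide isotopologue tables for a two-age by
# three-diet heavy-leucine labeling design with known ground truth, and
# synthetic polysome absorbance traces. Everything downstream of raw
# spectra is emulated; spectra, chromatography and identification are not.

# Average amino-acid frequencies in vertebrate proteins; used to draw
# realistic tryptic-peptide compositions (leucine ~10%, so a typical
# 8-18mer carries 0-3 label sites).
.aa_freq <- c(A = 0.074, R = 0.042, N = 0.044, D = 0.059, C = 0.033,
              E = 0.058, Q = 0.037, G = 0.074, H = 0.029, I = 0.038,
              L = 0.076, K = 0.072, M = 0.018, F = 0.040, P = 0.050,
              S = 0.081, T = 0.062, W = 0.013, Y = 0.033, V = 0.068)

#' Default simulation configuration
#'
#' The default design mirrors a two-age (young/old) by three-diet
#' (control, calorie-restricted, rapamycin) mouse labeling study: six
#' cohorts, four labeling timepoints at 3, 7, 12 and 17 days, three mice
#' per timepoint (12 mice per cohort). Half-lives are log-normal with a
#' median of 3.1 days in the young-control cohort; calorie restriction
#' multiplies half-lives by 1.6, rapamycin by 1.15, and age by 0.9.
#'
#' @param n_proteins Number of proteins.
#' @param peptides_per_protein Integer range (min, max) of peptides drawn
#'   per protein.
#' @param peptide_length Integer range of peptide lengths.
#' @param hl_median_days,hl_sigma Log-normal half-life distribution:
#'   median in days and log-scale standard deviation.
#' @param hl_multipliers Named multiplicative group effects on half-life,
#'   one per cohort.
#' @param abundance_multipliers Named multiplicative group effects on
#'   protein abundance (default all 1).
#' @param p_max,p_rate Precursor-pool enrichment curve
#'   `p(t) = p_max (1 - exp(-p_rate t))`.
#' @param timepoints Labeling days.
#' @param mice_per_timepoint Mice sacrificed per timepoint per cohort.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise applied per isotopologue intensity.
#' @param shared_fraction Fraction of peptides flagged as mapping to more
#'   than one protein (excluded from protein-level pooling downstream).
#' @param abundance_meanlog,abundance_sdlog Log-normal distribution of
#'   protein AUC abundance.
#' @param seed Random seed; the output is deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 300L,
                       peptides_per_protein = c(2L, 4L),
                       peptide_length = c(8L, 18L),
                       hl_median_days = 3.1,
                       hl_sigma = 0.8,
                       hl_multipliers = c(YCL = 1, YCR = 1.6, YRP = 1.15,
                                          OCL = 0.9, OCR = 1.3, ORP = 1.04),
                       abundance_multipliers = NULL,
                       p_max = 0.6,
                       p_rate = 0.35,
                       timepoints = c(3, 7, 12, 17),
                       mice_per_timepoint = 3L,
                       noise_cv = 0.05,
                       shared_fraction = 0.05,
                       abundance_meanlog = log(1e6),
                       abundance_sdlog = 1,
                       seed = 1L) {
  if (is.null(abundance_multipliers)) {
    abundance_multipliers <- stats::setNames(rep(1, length(hl_multipliers)),
                                             names(hl_multipliers))
  }
  stopifnot(n_proteins >= 1, all(hl_multipliers > 0),
            all(abundance_multipliers > 0), p_max > 0, p_max <= 1,
            p_rate > 0, all(timepoints > 0), mice_per_timepoint >= 1,
            noise_cv >= 0, !is.null(names(hl_multipliers)))
  cfg <- list(n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              peptide_length = as.integer(peptide_length),
              hl_median_days = hl_median_days, hl_sigma = hl_sigma,
              hl_multipliers = hl_multipliers,
              abundance_multipliers = abundance_multipliers,
              p_max = p_max, p_rate = p_rate, timepoints = timepoints,
              mice_per_timepoint = as.integer(mice_per_timepoint),
              noise_cv = noise_cv, shared_fraction = shared_fraction,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Precursor-pool enrichment curve
#'
#' Saturating exponential rise of the labeled fraction of the free
#' leucine pool after the diet switch: `p(t) = p_max (1 - exp(-rate t))`,
#' with `p(0) = 0`.
#'
#' @param p_max Plateau enrichment in (0, 1\].
#' @param rate Rise rate per day (> 0).
#' @param t Time(s) in days.
#' @return Enrichment value(s) in \[0, p_max\].
#' @export
simulate_enrichment_curve <- function(p_max, rate, t) {
  stopifnot(p_max > 0, p_max <= 1, rate > 0, all(t >= 0))
  p_max * (1 - exp(-rate * t))
}

#' Simulate a labeling study cohort table with ground truth
#'
#' For every protein, cohort and mouse at labeling day t the true
#' fraction-new is `f = 1 - exp(-t ln2 / HL)`; each peptide's expected
#' isotopologue vector is `AUC * ((1 - f) natural + f labeled(p(t)))`
#' with independent multiplicative log-normal noise (unit mean) at the
#' configured CV applied per isotopologue. Protein abundance is
#' time-independent (steady state).
#'
#' @param config A [sim_config()].
#' @return List with `observations` (data.frame with columns `peptide`,
#'   `protein`, `unique`, `sample`, `cohort`, `day`, `n_leucines`,
#'   `total_auc` and list-column `intensities`) and `truth` (list:
#'   per-protein per-cohort `HL` and abundance, per-sample enrichment).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cohorts <- names(config$hl_multipliers)

  proteins <- sprintf("P%04d", seq_len(config$n_proteins))
  base_hl <- stats::rlnorm(config$n_proteins,
                           meanlog = log(config$hl_median_days),
                           sdlog = config$hl_sigma)
  base_ab <- stats::rlnorm(config$n_proteins,
                           meanlog = config$abundance_meanlog,
                           sdlog = config$abundance_sdlog)

  n_pep <- sample(config$peptides_per_protein[1]:config$peptides_per_protein[2],
                  config$n_proteins, replace = TRUE)
  pep_protein <- rep(proteins, n_pep)
  lens <- sample(config$peptide_length[1]:config$peptide_length[2],
                 sum(n_pep), replace = TRUE)
  sequences <- vapply(lens, function(l) {
    paste(sample(names(.aa_freq), l, replace = TRUE, prob = .aa_freq),
          collapse = "")
  }, character(1))
  # disambiguate the (unlikely) duplicate draw so sequence keys are unique
  while (anyDuplicated(sequences)) {
    dup <- duplicated(sequences)
    sequences[dup] <- vapply(lens[dup], function(l) {
      paste(sample(names(.aa_freq), l, replace = TRUE, prob = .aa_freq),
            collapse = "")
    }, character(1))
  }
  n_leu <- vapply(sequences, count_label_sites, integer(1), USE.NAMES = FALSE)
  is_unique <- as.integer(stats::runif(sum(n_pep)) >= config$shared_fraction)
  # peptide share of its protein's AUC (flyability), fixed across samples
  share <- stats::rgamma(sum(n_pep), shape = 2)
  share <- share / as.numeric(tapply(share, pep_protein, sum)[pep_protein])
  pep_auc0 <- base_ab[match(pep_protein, proteins)] * share

  cache <- envelope_cache()
  sigma <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0

  p_by_day <- simulate_enrichment_curve(config$p_max, config$p_rate,
                                        config$timepoints)
  names(p_by_day) <- as.character(config$timepoints)

  n_pep_total <- length(sequences)
  out <- vector("list", length(cohorts) * length(config$timepoints) *
                  config$mice_per_timepoint)
  truth_hl <- outer(base_hl, config$hl_multipliers)
  rownames(truth_hl) <- proteins
  truth_ab <- outer(base_ab, config$abundance_multipliers)
  rownames(truth_ab) <- proteins
  sample_ids <- character(0)
  sample_p <- numeric(0)

  idx <- 0L
  for (co in cohorts) {
    hl_co <- truth_hl[, co]
    ab_mult <- config$abundance_multipliers[[co]]
    for (t in config$timepoints) {
      p_t <- p_by_day[[as.character(t)]]
      f_true <- 1 - exp(-t * log(2) / hl_co)
      f_pep <- f_true[match(pep_protein, proteins)]
      # expected (noise-free) intensity vectors, shared by this
      # timepoint's mice
      mu_list <- vector("list", n_pep_total)
      for (j in seq_len(n_pep_total)) {
        pre <- cache(sequences[j])
        env <- if (pre$L > 0 && p_t > 0) {
          lab <- drop(stats::dbinom(0:pre$L, pre$L, p_t) %*% pre$S)
          (1 - f_pep[j]) * pre$nat + f_pep[j] * lab / sum(lab)
        } else pre$nat
        mu_list[[j]] <- pep_auc0[j] * ab_mult * env
      }
      for (r in seq_len(config$mice_per_timepoint)) {
        sid <- sprintf("%s_d%02d_m%d", co, t, r)
        sample_ids <- c(sample_ids, sid)
        sample_p <- c(sample_p, p_t)
        intens <- if (sigma > 0) {
          lapply(mu_list, function(mu) {
            mu * exp(stats::rnorm(length(mu), -sigma^2 / 2, sigma))
          })
        } else mu_list
        idx <- idx + 1L
        blk <- data.frame(peptide = sequences, protein = pep_protein,
                          unique = is_unique, sample = sid, cohort = co,
                          day = t, n_leucines = n_leu,
                          stringsAsFactors = FALSE)
        blk$intensities <- intens
        blk$total_auc <- vapply(intens, sum, numeric(1))
        out[[idx]] <- blk
      }
    }
  }
  observations <- do.call(rbind, out)
  rownames(observations) <- NULL
  list(observations = observations,
       truth = list(HL = truth_hl, abundance = truth_ab,
                    enrichment = data.frame(sample = sample_ids, p = sample_p,
                                            stringsAsFactors = FALSE),
                    config = config))
}

#' Simulate a polysome absorbance trace
#'
#' Sum of Gaussian peaks with the given areas plus a linear baseline and
#' iid Gaussian noise, sampled on an even position grid.
#'
#' @param areas Peak areas (>= 0), ordered top of gradient first.
#' @param centers Peak center positions (strictly increasing).
#' @param widths Gaussian standard deviations (recycled).
#' @param baseline Length-2 `c(intercept, slope)` linear baseline.
#' @param noise_sd Standard deviation of additive noise.
#' @param n_points Samples along the trace.
#' @param xlim Position range.
#' @param seed Optional seed for the noise (deterministic trace if set).
#' @return Data.frame `position`, `absorbance`; attribute
#'   `overlap_warning` is `TRUE` when adjacent centers lie closer than
#'   one standard deviation (valley segmentation may merge such peaks).
#' @export
simulate_polysome_trace <- function(areas, centers, widths,
                                    baseline = c(0, 0), noise_sd = 0,
                                    n_points = 2000L,
                                    xlim = range(centers) + c(-4, 4) * max(widths),
                                    seed = NULL) {
  stopifnot(all(areas >= 0), all(diff(centers) > 0),
            length(areas) == length(centers))
  widths <- rep_len(widths, length(centers))
  if (!is.null(seed)) set.seed(seed)
  x <- seq(xlim[1], xlim[2], length.out = n_points)
  y <- baseline[1] + baseline[2] * x
  for (i in seq_along(centers)) {
    y <- y + areas[i] * stats::dnorm(x, centers[i], widths[i])
  }
  if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
  trace <- data.frame(position = x, absorbance = y)
  overlap <- any(diff(centers) < pmax(utils::head(widths, -1),
                                      utils::tail(widths, -1)))
  if (overlap) warning("adjacent peak centers closer than one width; ",
                       "valley segmentation may merge peaks")
  attr(trace, "overlap_warning") <- overlap
  trace
}
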