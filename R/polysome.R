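# Polysome-profile quantification: baseline correction of A254 traces,
# valley segmentation of the 40S/60S/80S/polysome peaks, trapezoidal peak
# areas and trend tests across ribosome loading.

#' Baseline-correct an absorbance trace
#'
#' Subtracts the straight line through the trace's flanking minima (the
#' lowest point in the first and last `flank` fraction of samples) and
#' clips the result at zero. Invariant to adding any constant or linear
#' ramp whose flanks carry no peaks.
#'
#' @param trace Data.frame with strictly increasing `position` and
#'   `absorbance` columns, at least 50 samples.
#' @param flank Fraction of the trace length used as each anchoring
#'   window (default 0.1).
#' @return The trace with corrected `absorbance`.
#' @export
baseline_correct <- function(trace, flank = 0.1) {
  .check_trace(trace)
  n <- nrow(trace)
  stopifnot(n >= 50)
  k <- max(2L, floor(flank * n))
  i1 <- which.min(trace$absorbance[seq_len(k)])
  i2 <- n - k + which.min(trace$absorbance[(n - k + 1L):n])
  x1 <- trace$position[i1]; y1 <- trace$absorbance[i1]
  x2 <- trace$position[i2]; y2 <- trace$absorbance[i2]
  slope <- (y2 - y1) / (x2 - x1)
  base <- y1 + slope * (trace$position - x1)
  trace$absorbance <- pmax(trace$absorbance - base, 0)
  trace
}

.check_trace <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("position", "absorbance") %in% names(trace)),
            nrow(trace) == length(trace$absorbance),
            all(diff(trace$position) > 0))
}

#' Segment a polysome trace into labeled peaks
#'
#' Finds local maxima above a prominence threshold and places segment
#' boundaries at the deepest valley between consecutive maxima. The first
#' three peaks (top of gradient first) are labeled 40S, 60S and 80S, the
#' following ones 2, 3, 4 ribosomes, and everything beyond the 6th peak is
#' pooled into a single ">=5" segment running to the end of the trace.
#'
#' @param trace Baseline-corrected trace.
#' @param n_expected Number of labeled segments expected (default 7:
#'   40S, 60S, 80S, 2, 3, 4, >=5).
#' @param prominence Minimum peak prominence as a fraction of the maximum
#'   absorbance (default 0.02).
#' @return Data.frame with one row per segment: `label`, `start`, `end`
#'   (positions), `peak_position`.
#' @export
detect_peaks <- function(trace, n_expected = 7L, prominence = 0.02) {
  .check_trace(trace)
  y <- trace$absorbance
  x <- trace$position
  maxima <- .local_maxima(y, prominence * max(y))
  if (length(maxima) < n_expected) {
    stop("found only ", length(maxima), " peak(s) at positions ",
         paste(signif(x[maxima], 4), collapse = ", "),
         " but expected ", n_expected, " segments")
  }
  labels <- c("40S", "60S", "80S", "2", "3", "4")
  n_named <- min(length(maxima), 6L)
  # valley (deepest minimum) between consecutive kept maxima
  cuts <- vapply(seq_len(length(maxima) - 1L), function(i) {
    span <- maxima[i]:maxima[i + 1L]
    span[which.min(y[span])]
  }, integer(1))
  seg_start <- c(1L, cuts)
  seg_end <- c(cuts, length(y))
  seg <- data.frame(
    label = c(labels[seq_len(n_named)],
              rep(">=5", length(maxima) - n_named)),
    start = x[seg_start], end = x[seg_end],
    peak_position = x[maxima], stringsAsFactors = FALSE)
  if (any(seg$label == ">=5")) {
    pool <- seg$label == ">=5"
    pooled <- data.frame(label = ">=5", start = min(seg$start[pool]),
                         end = max(seg$end[pool]),
                         peak_position = seg$peak_position[which(pool)[1]],
                         stringsAsFactors = FALSE)
    seg <- rbind(seg[!pool, ], pooled)
  }
  if (nrow(seg) != n_expected) {
    stop("segmentation produced ", nrow(seg), " segments, expected ",
         n_expected)
  }
  rownames(seg) <- NULL
  seg
}

# indices of local maxima with prominence above `min_prom`; prominence is
# height above the higher of the two bounding valleys (valley = lowest
# point before a higher peak or the trace end is reached)
.local_maxima <- function(y, min_prom) {
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  # a flat-topped peak yields one candidate per plateau edge; keep the first
  if (length(cand) > 1) {
    drop <- logical(length(cand))
    for (j in 2:length(cand)) {
      i <- cand[j]
      while (i > 1L && y[i - 1L] == y[i]) i <- i - 1L
      drop[j] <- i <= cand[j - 1L] && !drop[j - 1L]
    }
    cand <- cand[!drop]
  }
  keep <- vapply(cand, function(i) {
    lo <- i; base_l <- y[i]
    while (lo > 1L && y[lo - 1L] <= y[i]) { lo <- lo - 1L; base_l <- min(base_l, y[lo]) }
    hi <- i; base_r <- y[i]
    while (hi < n && y[hi + 1L] <= y[i]) { hi <- hi + 1L; base_r <- min(base_r, y[hi]) }
    y[i] - max(base_l, base_r) >= min_prom
  }, logical(1))
  cand[keep]
}

#' Per-segment trapezoidal areas and ratios to total
#'
#' @param trace Baseline-corrected trace.
#' @param peaks Segment table from [detect_peaks()].
#' @return Data.frame `label`, `auc`, `ratio_to_total` (ratios sum to 1).
#' @export
peak_areas <- function(trace, peaks) {
  .check_trace(trace)
  auc <- vapply(seq_len(nrow(peaks)), function(i) {
    sel <- trace$position >= peaks$start[i] & trace$position <= peaks$end[i]
    .trapz(trace$position[sel], trace$absorbance[sel])
  }, numeric(1))
  data.frame(label = peaks$label, auc = auc,
             ratio_to_total = auc / sum(auc), stringsAsFactors = FALSE)
}

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Percent-of-control peak ratios
#'
#' Expresses each sample's per-segment area ratios as a percent of the
#' mean control-cohort ratio for the same segment.
#'
#' @param areas Data.frame with `sample`, `label`, `ratio_to_total` for
#'   treated samples.
#' @param control_areas Same columns for the control cohort.
#' @return `areas` with a `percent_of_control` column appended.
#' @export
percent_of_control <- function(areas, control_areas) {
  ctrl <- tapply(control_areas$ratio_to_total, control_areas$label, mean)
  areas$percent_of_control <- 100 * areas$ratio_to_total /
    as.numeric(ctrl[areas$label])
  areas
}

#' Linear trend of peak ratios across ribosome loading
#'
#' Regresses percent-of-control values on the integer loading index
#' (segments ordered from fewest to most ribosomes) and tests the slope
#' two-sided. A coordinated decline of the heavier polysome fractions
#' appears as a significant negative slope.
#'
#' @param values Numeric vector of percent-of-control values.
#' @param loading Integer loading index for each value (>= 4 distinct
#'   classes, >= 2 replicates per class).
#' @return List `slope`, `se`, `p_value`, `n`, `degenerate` (residual
#'   variance numerically zero; `p_value` then reported as below machine
#'   precision).
#' @export
loading_trend_test <- function(values, loading) {
  stopifnot(length(values) == length(loading))
  tab <- table(loading)
  if (length(tab) < 4L) stop("need >= 4 ordered loading classes")
  if (any(tab < 2L)) stop("need >= 2 replicates per loading class")
  x <- as.numeric(loading); y <- values; n <- length(y)
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  res <- y - mean(y) - slope * xc
  rss <- sum(res^2)
  degenerate <- rss <= 1e-12 * sum((y - mean(y))^2) || rss == 0
  if (degenerate) {
    return(list(slope = slope, se = 0,
                p_value = .Machine$double.xmin, n = n, degenerate = TRUE))
  }
  se <- sqrt(rss / (n - 2L) / sum(xc^2))
  tstat <- slope / se
  list(slope = slope, se = se, p_value = 2 * stats::pt(-abs(tstat), n - 2L),
       n = n, degenerate = FALSE)
}
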