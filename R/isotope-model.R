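.pt_env <- new.env(parent = emptyenv())

#' Residue elemental-composition table
#'
#' Reads the residue composition table shipped with the package (or a
#' user-supplied replacement). Each row gives the elemental composition of
#' one amino-acid residue, i.e. the free amino acid minus one water; an
#' intact peptide of n residues is the sum of its residue rows plus one
#' H2O (N-terminal H, C-terminal OH).
#'
#' @param path Optional path to an alternative TSV with columns
#'   `residue, C, H, N, O, S`.
#' @return A data.frame with one row per residue, rownames set to the
#'   one-letter code.
#' @export
residue_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pt_env$residue_table)) return(.pt_env$residue_table)
    path <- system.file("extdata", "residue_composition.tsv",
                        package = "proteoturn", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "C", "H", "N", "O", "S") %in% names(tab)))
  rownames(tab) <- tab$residue
  if (is.null(.pt_env$residue_table)) .pt_env$residue_table <- tab
  tab
}

#' Isotope abundance table
#'
#' Terrestrial isotope abundances for C, H, N, O and S keyed by nominal
#' mass offset from the lightest isotope. Abundances for each element sum
#' to one. The table is plain TSV so tests can substitute degenerate
#' single-isotope tables.
#'
#' @param path Optional path to an alternative TSV with columns
#'   `element, offset, abundance`.
#' @return A named list, one numeric vector per element; element `i` of the
#'   vector is the abundance at offset `i - 1` (zeros fill unused offsets).
#' @export
isotope_table <- function(path = NULL) {
  if (is.null(path) && !is.null(.pt_env$isotope_table)) {
    return(.pt_env$isotope_table)
  }
  fp <- path
  if (is.null(fp)) {
    fp <- system.file("extdata", "isotope_abundance.tsv",
                      package = "proteoturn", mustWork = TRUE)
  }
  raw <- utils::read.delim(fp, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "offset", "abundance") %in% names(raw)))
  tab <- lapply(split(raw, raw$element), function(d) {
    d <- d[order(d$offset), ]
    if (any(duplicated(d$offset))) stop("duplicated isotope offsets")
    v <- numeric(max(d$offset) + 1L)
    v[d$offset + 1L] <- d$abundance
    if (abs(sum(v) - 1) > 1e-12) {
      stop("isotope abundances for ", d$element[1], " do not sum to 1")
    }
    v
  })
  if (is.null(path)) .pt_env$isotope_table <- tab
  tab
}

#' Elemental composition of a peptide
#'
#' Sums residue compositions and adds one water for the terminal H and OH.
#'
#' @param sequence Peptide as an uppercase one-letter amino-acid string.
#' @param residues Residue table, see [residue_table()].
#' @return Named integer vector with counts for C, H, N, O, S.
#' @examples
#' composition_from_sequence("PEPTIDE")
#' @export
composition_from_sequence <- function(sequence, residues = residue_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), rownames(residues))
  if (length(bad) > 0) {
    stop("unknown residue(s) in sequence: ", paste(bad, collapse = ", "))
  }
  counts <- colSums(residues[aa, c("C", "H", "N", "O", "S"), drop = FALSE])
  counts["H"] <- counts["H"] + 2L  # terminal H / OH
  counts["O"] <- counts["O"] + 1L
  storage.mode(counts) <- "integer"
  counts
}

#' Number of label sites in a peptide
#'
#' Heavy label is carried on leucine only; isoleucine is never counted.
#'
#' @inheritParams composition_from_sequence
#' @return Integer count of leucine residues.
#' @export
count_label_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sum(strsplit(sequence, "")[[1]] == "L")
}

# Convolve a distribution with itself n times, truncating at max_offset.
# Offsets are non-negative, so truncation at each step is exact for the
# retained entries (mass can only move upward).
.conv_pow <- function(dist, n, max_offset) {
  len <- max_offset + 1L
  base <- numeric(len)
  base[seq_len(min(length(dist), len))] <- dist[seq_len(min(length(dist), len))]
  out <- c(1, numeric(max_offset))
  while (n > 0) {
    if (n %% 2 == 1) out <- .conv_trunc(out, base, len)
    n <- n %/% 2
    if (n > 0) base <- .conv_trunc(base, base, len)
  }
  out
}

.conv_trunc <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    k <- len - i + 1L
    out[i:len] <- out[i:len] + a[i] * b[seq_len(k)]
  }
  out
}

#' Natural-abundance isotopologue envelope
#'
#' Convolves the per-atom isotope distributions over all atoms of a
#' composition. Entry 1 of the result is the monoisotopic species (offset
#' 0); the envelope is truncated at `max_offset` and renormalized to sum
#' to one.
#'
#' @param composition Named counts per element, as returned by
#'   [composition_from_sequence()].
#' @param max_offset Largest nominal mass offset retained (>= 0).
#' @param isotopes Isotope table, see [isotope_table()].
#' @return Numeric vector of length `max_offset + 1` summing to one.
#' @export
natural_envelope <- function(composition, max_offset,
                             isotopes = isotope_table()) {
  stopifnot(max_offset >= 0, all(composition >= 0))
  env <- c(1, numeric(max_offset))
  for (el in names(composition)) {
    n <- composition[[el]]
    if (n == 0) next
    if (is.null(isotopes[[el]])) stop("no isotope data for element ", el)
    env <- .conv_trunc(env, .conv_pow(isotopes[[el]], n, max_offset),
                       max_offset + 1L)
  }
  env / sum(env)
}

#' Isotopologue envelope of newly synthesized peptide
#'
#' A peptide synthesized entirely from a precursor pool at enrichment `p`
#' carries a Binomial(L, p) number of heavy leucines; each heavy leucine
#' (2H3) shifts the natural envelope by +3 nominal offsets. The mass defect
#' between 3x2H and 3x13C (~0.009 Da) is below unit resolution and is
#' ignored. The mixture is truncated at `max_offset` and renormalized.
#'
#' @param sequence Peptide sequence (uppercase one-letter codes).
#' @param p Precursor-pool enrichment in \[0, 1\].
#' @param max_offset Largest offset retained; default `3 * L + 6` captures
#'   essentially all mass for tryptic peptides.
#' @param isotopes,residues Lookup tables, overridable for testing.
#' @return Numeric vector of length `max_offset + 1` summing to one.
#' @export
labeled_envelope <- function(sequence, p,
                             max_offset = 3L * count_label_sites(sequence) + 6L,
                             isotopes = isotope_table(),
                             residues = residue_table()) {
  stopifnot(p >= 0, p <= 1)
  L <- count_label_sites(sequence)
  nat <- natural_envelope(composition_from_sequence(sequence, residues),
                          max_offset, isotopes)
  mix_labeled_envelope(nat, L, p)
}

# Shifted-mixture core shared with the deconvolution fits: `nat` is a
# natural envelope already truncated to the working window. Each shifted
# component is renormalized within the window before binomial mixing so the
# forward model and the mixture fit see exactly the same envelopes.
mix_labeled_envelope <- function(nat, L, p) {
  w <- stats::dbinom(0:L, L, p)
  out <- drop(w %*% shift_matrix(nat, L))
  out / sum(out)
}

# Matrix of the natural envelope shifted by 0, 3, ..., 3L offsets, rows
# renormalized; used to evaluate many enrichment values cheaply.
shift_matrix <- function(nat, L) {
  len <- length(nat)
  stopifnot(len > 3L * L)
  S <- matrix(0, nrow = L + 1L, ncol = len)
  for (h in 0:L) {
    s <- 3L * h
    if (s >= len) break
    S[h + 1L, (s + 1L):len] <- nat[seq_len(len - s)]
  }
  S / rowSums(S)
}
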