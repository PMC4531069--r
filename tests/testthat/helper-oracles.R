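# Independent oracles and small fixture builders shared across tests.

# --- multinomial isotopologue-envelope oracle -------------------------------
# Computes the envelope from per-element multinomial isotope-count
# distributions (exact closed form), combined across elements by explicit
# offset enumeration. Independent of the package's atom-wise convolution.

.oracle_compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  do.call(rbind, lapply(0:n, function(i) {
    cbind(i, .oracle_compositions(n - i, k - 1))
  }))
}

.oracle_element_dist <- function(n, offsets, probs) {
  cc <- .oracle_compositions(n, length(offsets))
  off <- as.vector(cc %*% offsets)
  pr <- apply(cc, 1, function(ct) stats::dmultinom(ct, prob = probs))
  tapply(pr, off, sum)
}

oracle_envelope <- function(sequence, max_offset) {
  comp <- composition_from_sequence(sequence)
  iso <- utils::read.delim(system.file("extdata", "isotope_abundance.tsv",
                                       package = "proteoturn"))
  total <- c(`0` = 1)
  for (el in names(comp)) {
    n <- comp[[el]]
    if (n == 0) next
    d <- iso[iso$element == el, ]
    ed <- .oracle_element_dist(n, d$offset, d$abundance)
    grid <- expand.grid(a = as.integer(names(total)),
                        b = as.integer(names(ed)))
    off <- grid$a + grid$b
    pr <- as.numeric(total[as.character(grid$a)]) *
      as.numeric(ed[as.character(grid$b)])
    total <- tapply(pr, off, sum)
    # offsets are non-negative, so dropping entries beyond the window is
    # exact for the retained ones
    total <- total[as.integer(names(total)) <= max_offset]
  }
  v <- numeric(max_offset + 1)
  v[as.integer(names(total)) + 1] <- as.numeric(total)
  v / sum(v)
}

# --- observation builders ---------------------------------------------------

# one noiseless observation at given fraction-new and enrichment
make_obs <- function(sequence, f, p, A = 1e6, sample = "s1", cohort = "X",
                     day = 7, protein = "prot1", unique = 1L) {
  L <- count_label_sites(sequence)
  nat <- natural_envelope(composition_from_sequence(sequence), 3L * L + 6L)
  env <- if (L > 0 && p > 0) {
    (1 - f) * nat + f * labeled_envelope(sequence, p)
  } else nat
  obs <- data.frame(peptide = sequence, protein = protein, unique = unique,
                    sample = sample, cohort = cohort, day = day,
                    n_leucines = L, stringsAsFactors = FALSE)
  obs$intensities <- list(A * env)
  obs$total_auc <- A
  obs
}

make_obs_table <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# random peptide with at least `min_leu` leucines
random_peptide <- function(len, min_leu = 0) {
  aas <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  repeat {
    s <- paste(sample(aas, len, replace = TRUE), collapse = "")
    if (count_label_sites(s) >= min_leu) return(s)
  }
}
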