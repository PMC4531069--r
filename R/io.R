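# Readers/writers for the pipeline's plain-text tables. Isotopologue
# intensity vectors travel as a single semicolon-delimited column so a
# whole study fits in one diff-able TSV.

.required_cols <- c("peptide", "protein", "unique", "sample", "cohort",
                    "day", "intensities")

#' Read a peptide isotopologue quant table
#'
#' Expects TSV (or CSV, by file extension) with columns `peptide`,
#' `protein`, `unique` (0/1), `sample`, `cohort`, `day` and
#' `intensities` (semicolon-delimited floats, offset 0 first). Derived
#' columns `n_leucines` and `total_auc` are recomputed on read.
#'
#' @param path Input file.
#' @return Observation data.frame with `intensities` as a list-column.
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.required_cols, names(tab))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  intens <- lapply(strsplit(as.character(tab$intensities), ";", fixed = TRUE),
                   as.numeric)
  bad <- which(vapply(intens, function(v) {
    length(v) == 0 || any(is.na(v)) || any(v < 0)
  }, logical(1)))
  if (length(bad) > 0) {
    warning(length(bad), " malformed row(s) rejected (negative or ",
            "unparseable intensities) at data line(s): ",
            paste(utils::head(bad, 10), collapse = ", "))
    tab <- tab[-bad, , drop = FALSE]
    intens <- intens[-bad]
  }
  out <- data.frame(peptide = as.character(tab$peptide),
                    protein = as.character(tab$protein),
                    unique = as.integer(tab$unique),
                    sample = as.character(tab$sample),
                    cohort = as.character(tab$cohort),
                    day = as.numeric(tab$day),
                    stringsAsFactors = FALSE)
  out$n_leucines <- vapply(out$peptide, count_label_sites, integer(1),
                           USE.NAMES = FALSE)
  out$intensities <- intens
  out$total_auc <- vapply(intens, sum, numeric(1))
  if (any(out$day < 0)) stop("negative labeling day")
  out
}

#' Write a peptide observation table
#'
#' Inverse of [read_peptide_table()]: serializes the intensity
#' list-column to semicolon-delimited strings.
#'
#' @param observations Observation data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(observations, path) {
  tab <- observations[c("peptide", "protein", "unique", "sample",
                        "cohort", "day")]
  tab$intensities <- vapply(observations$intensities, function(v) {
    paste(format(v, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = ";")
  }, character(1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a protein-to-pathway mapping table
#'
#' @param path TSV with columns `protein`, `pathway` and optionally
#'   `category` (pathway or compartment).
#' @return Data.frame.
#' @export
read_pathway_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("protein", "pathway"), names(tab))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

#' Read a polysome trace
#'
#' @param path Two-column CSV `position, absorbance` (header optional but
#'   recommended).
#' @return Trace data.frame.
#' @export
read_polysome_trace <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("position", "absorbance") %in% names(tab))) {
    stop("trace must have columns 'position' and 'absorbance'")
  }
  .check_trace(tab)
  tab
}

#' Run the full turnover pipeline on an observation table
#'
#' Executes the stages in order: per-sample enrichment estimation,
#' per-peptide fraction-new at the fixed sample enrichment, unique-peptide
#' pooling to protein time courses, first-order fits per protein and
#' cohort, all pairwise cohort comparisons against the reference cohort
#' (half-life ratios, proportion z-test, slope difference tests with BH
#' q-values, differential abundance), and optional pathway summaries.
#'
#' @param observations Observation table (from [read_peptide_table()] or
#'   [simulate_cohort()]).
#' @param reference Reference cohort id for pairwise comparisons (default
#'   the first cohort in the table).
#' @param pathway_mapping Optional mapping data.frame (`protein`,
#'   `pathway`).
#' @param min_points,q_threshold,signal_floor,enrichment_n_max Stage
#'   parameters, see the stage functions.
#' @param out_dir Optional directory; when given, every stage table plus a
#'   JSON run manifest is written there as TSV.
#' @return List with `enrichment`, `percent_new`, `pooled`, `fits` (per
#'   cohort), `comparisons` (per non-reference cohort: `ratios`, `ztest`,
#'   `hl_test`, `abundance`), `matrix` (log2 HL-ratio matrix at the q
#'   threshold), and `pathways` (when a mapping was given).
#' @export
run_pipeline <- function(observations, reference = NULL,
                         pathway_mapping = NULL, min_points = 4L,
                         q_threshold = 0.05, signal_floor = 0,
                         enrichment_n_max = 200L, out_dir = NULL) {
  stopifnot(q_threshold > 0, q_threshold < 1)
  cohorts <- unique(observations$cohort)
  if (is.null(reference)) reference <- cohorts[1]
  stopifnot(reference %in% cohorts)

  enrichment <- do.call(rbind, lapply(split(observations,
                                            observations$sample),
    function(obs) {
      est <- estimate_sample_enrichment(obs, signal_floor = signal_floor,
                                        n_max = enrichment_n_max)
      data.frame(sample = est$sample, p = est$p,
                 n_peptides_used = est$n_peptides_used,
                 dispersion = est$dispersion, stringsAsFactors = FALSE)
    }))
  rownames(enrichment) <- NULL

  percent_new <- do.call(rbind, lapply(split(observations,
                                             observations$sample),
    function(obs) {
      p <- enrichment$p[enrichment$sample == obs$sample[1]]
      percent_new_per_peptide(obs, p, signal_floor = signal_floor)
    }))
  rownames(percent_new) <- NULL

  pooled <- pool_protein_fraction_new(percent_new)
  fits <- lapply(split(pooled, pooled$cohort), fit_turnover,
                 min_points = min_points)

  comparisons <- list()
  for (co in setdiff(cohorts, reference)) {
    ratios <- compute_hl_ratios(fits[[co]], fits[[reference]],
                                labels = c(co, reference))
    hl_test <- hl_difference_test(fits[[co]], fits[[reference]])
    comparisons[[paste0(co, "/", reference)]] <- list(
      ratios = ratios,
      ztest = ratio_proportion_ztest(ratios),
      hl_test = hl_test,
      abundance = differential_abundance(
        observations[observations$cohort == co, ],
        observations[observations$cohort == reference, ]))
  }

  mat <- if (length(comparisons) > 0) {
    comparison_matrix(lapply(comparisons, function(cmp) {
      merge(cmp$ratios[c("protein", "log2_ratio")],
            cmp$hl_test[c("protein", "q_value")], by = "protein")
    }), q_threshold = q_threshold)
  } else NULL

  pathways <- if (!is.null(pathway_mapping)) {
    pathway_summary(fits, pathway_mapping)
  } else NULL

  result <- list(enrichment = enrichment, percent_new = percent_new,
                 pooled = pooled, fits = fits, comparisons = comparisons,
                 matrix = mat, pathways = pathways,
                 parameters = list(reference = reference,
                                   min_points = min_points,
                                   q_threshold = q_threshold,
                                   signal_floor = signal_floor,
                                   enrichment_n_max = enrichment_n_max))
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write all pipeline stage outputs plus a run manifest
#'
#' @param result A [run_pipeline()] result bundle.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, name) {
    utils::write.table(d, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$enrichment, "enrichment.tsv")
  wt(result$percent_new, "percent_new.tsv")
  wt(result$pooled, "protein_fraction_new.tsv")
  all_fits <- do.call(rbind, result$fits)
  rownames(all_fits) <- NULL
  wt(all_fits, "half_lives.tsv")
  for (nm in names(result$comparisons)) {
    cmp <- result$comparisons[[nm]]
    tag <- gsub("/", "_vs_", nm, fixed = TRUE)
    wt(cmp$ratios, paste0("hl_ratios_", tag, ".tsv"))
    wt(cmp$hl_test, paste0("hl_test_", tag, ".tsv"))
    wt(cmp$abundance, paste0("abundance_", tag, ".tsv"))
  }
  if (!is.null(result$matrix) && nrow(result$matrix) > 0) {
    utils::write.table(data.frame(protein = rownames(result$matrix),
                                  result$matrix, check.names = FALSE),
                       file.path(out_dir, "log2_ratio_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$pathways)) wt(result$pathways, "pathway_summary.tsv")
  manifest <- list(
    package = "proteoturn",
    version = as.character(utils::packageVersion("proteoturn")),
    parameters = result$parameters,
    n_samples = nrow(result$enrichment),
    cohorts = names(result$fits),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
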