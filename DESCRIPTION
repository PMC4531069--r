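Package: proteoturn
Title: Protein Turnover Kinetics from Stable-Isotope Metabolic Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vivo protein turnover measured by
    heavy-leucine metabolic labeling and LC-MS/MS. Computes peptide
    isotopologue envelopes from elemental composition, deconvolutes observed
    isotopologue intensity vectors into old/new protein mixtures while
    estimating the precursor-pool enrichment, fits first-order appearance
    kinetics to obtain precursor-corrected protein half-lives, and provides
    between-group statistics (half-life ratios, slope difference tests with
    FDR control, differential abundance, pathway summaries, rank
    correlations). Also quantifies polysome-profile absorbance traces
    (baseline correction, peak segmentation, per-peak areas, loading trend
    tests) and ships a synthetic-data generator that emulates a two-age by
    three-diet labeling study with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
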