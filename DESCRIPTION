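Package: episcreen
Title: Matrix-Pooled Screening and Validation of Viral CD8+ T Cell Epitopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Plan and analyse multi-level CD8+ T cell epitope identification
    campaigns against the oncolytic virus VSV-GP in the BALB/c mouse model.
    Implements 8-11-mer candidate enumeration from an ordered viral proteome,
    predictor-score ranking with a gene-position quota gradient, a 7x7
    two-pool matrix design with deconvolution, IFN-gamma ELISpot positivity
    calling with a minimum spot-count floor, single-peptide confirmation,
    intracellular cytokine staining summaries (cross-assay correlation, route
    comparisons, epitope composition, polyfunctionality gates), epitope
    characterization (protein and length distributions, anchor-residue
    motifs, nested pairs, multimer eligibility), and a negative-binomial
    assay simulator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    emmeans,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
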