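Package: convar
Title: Convergent Cis-Regulatory Evolution in Hibernating Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics pipeline for detecting convergent
    cis-regulatory evolution in hibernating mammals. Calls conserved
    regions from a multi-species alignment with a two-state phylogenetic
    hidden Markov model, tests them for lineage-specific acceleration
    (likelihood-ratio test on the foreground terminal branch) and
    deletion, detects parallel events across independent hibernator
    lineages with a resampling null, assigns elements to genes through
    binned chromatin-contact maps, quantifies enrichment against
    regulatory annotations (odds ratios, Woolf heterogeneity,
    hypergeometric and locus-overlap tests), extracts co-expression hub
    genes, and scores differential transcription-factor motif content.
    Ships synthetic-data generators with machine-readable planted truth
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    withr,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
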