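Package: orthoverlap
Title: Cross-Species Tissue-Enrichment Overlap Testing for RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether a set of tissue-enriched genes in one
    species overlaps, more often than chance allows, with an independently
    defined gene set in a second species. Provides TPM normalisation and
    fold-change/p-value enrichment filtering of replicate RNA-seq abundance
    matrices, parsing of OrthoFinder orthogroup tables and restriction to
    single-copy orthogroups, projection of gene sets into orthogroup space,
    a seeded Monte Carlo overlap test (sampling without replacement) with an
    exact hypergeometric tail as analytic counterpart, an alien-index
    contamination screen over BLAST tabular reports, and a two-species
    synthetic data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
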