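Package: pharmtree
Title: Pharmacological Subtype Trees and Therapeutic-Response Similarity
Version: 0.1.0
Authors@R: person("pharmtree", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Re-classifies tumor cell lines by therapeutic response. Grows
    per-drug pharmacological subtype trees by recursive Mann-Whitney
    partitioning of ln-IC50 values, labels cells sensitive or resistant
    against the per-drug maximum screened concentration, derives cell-cell
    and drug-drug similarity from subtype co-membership and response
    concordance, and connects subtypes to genomic alterations and gene
    expression through chi-squared and t tests with Benjamini-Hochberg
    correction, assembling a directed gene-drug association network.
    Includes a seeded synthetic-cohort simulator with planted subtype
    structure for end-to-end validation, downstream clustering and
    enrichment statistics, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
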