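Package: catomics
Title: Multi-Omic Analysis Pipeline for Polyphenol-Driven Methane
    Suppression in Peat Microcosms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable computational stages for genome-resolved
    metatranscriptome and metabolome analysis of anaerobic peat
    microcosms amended with the polyphenol catechin. Provides
    gene-length-corrected TMM (geTMM) normalization with low-count and
    genome-activity filtering, a six-way classifier of MAG
    (metagenome-assembled genome) gene-expression responses across
    treatments, rule-based calling of methanogen substrate use and
    active methanogenesis pathways, a hydrogenase directionality atlas
    with class-level expression statistics, an exact stoichiometric
    ledger of the hydrogen economy of catechin and phloroglucinol
    degradation, an in-source-fragment and halogen filter for
    untargeted LC-MS feature tables, and multi-level community
    statistics (Bray-Curtis, PERMANOVA, Kruskal-Wallis with Dunn's
    post-hoc and Benjamini-Hochberg correction). A synthetic-data
    module generates every input with planted ground truth so the full
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
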