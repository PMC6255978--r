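Package: darkgenes
Title: Evidence Aggregation for Unannotated Genes in Toxicogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies differentially expressed genes per compound from log2
    expression matrices, audits their coverage across biological-process and
    pathway annotation resources (GO BP, Reactome, MSigDB, Pathway Commons,
    OmniPath) to tag "dark" genes lacking any such annotation, and assembles
    multi-source functional evidence for those genes: protein-interaction
    degrees across interactome snapshots, disease and literature counts,
    transcription-factor regulon and pathway-signature membership, and rat
    ortholog co-expression-module context. Evidence is combined into a
    per-gene binary matrix, sum score, tier, and drug-induced-liver-injury
    group-exclusivity flags. A seeded synthetic-data generator produces a
    complete fixture world with planted ground truth so the whole pipeline
    runs and is testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    limma,
    jsonlite
Config/testthat/edition: 3
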