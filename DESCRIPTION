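Package: evigraph
Title: Property-Graph Store and Traversal Query Engine for Cancer
    Genomics Evidence Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-memory property-graph store with a cancer-genomics
    evidence-graph schema (Program/Project/Case/Sample/Aliquot cohort
    trees, somatic callsets and alleles, pathways, compounds, drug
    response, gene expression, and literature-curated
    genotype-to-phenotype associations), a traversal-based graph query
    language with traveler semantics (marks, select, render, distinct,
    term aggregation), ETL loaders from standard bioinformatics formats
    (MAF-like TSV, GMT gene sets, expression matrices, drug-response
    CSV, association JSON Lines), a brute-force reference interpreter
    for differential testing, and a seeded synthetic mini-cohort
    generator with independently recorded ground truth for eight
    cookbook analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
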