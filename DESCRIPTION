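Package: tsgrank
Title: Tumor Suppressor Gene Prioritization from Network-Neighborhood
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encodes genes as -log10 hypergeometric enrichment scores of
    their protein-protein interaction neighborhoods against Gene Ontology
    and pathway gene sets, selects informative enrichment features with a
    Cramer's V prefilter followed by mRMR ranking and incremental feature
    selection under a dagging ensemble of linear support vector machines
    scored by the Matthews correlation coefficient, and ranks candidate
    tumor suppressor genes by counting selected features above a
    significance threshold.  Ships a seeded synthetic-data generator
    (interaction network, annotation catalogs, term DAG, planted causal
    terms) so the whole pipeline is testable without any database
    download, plus readers for STRING-style edge lists, GMT gene sets and
    is-a term DAGs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    fgsea,
    graphics,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
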