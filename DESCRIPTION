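Package: coexatlas
Title: Gene Co-Expression Atlas Construction from Transcriptomic Compendia
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and interrogates gene co-expression networks from a
    normalized expression compendium spanning many cultivation conditions.
    Computes all-pairs Spearman rank correlations with a permutation-null
    calibrated significance cutoff, extracts per-gene sub-networks at dual
    stringencies split into positive and negative partners, overlays
    experimentally validated informant ORFs for guilt-by-association
    function transfer, tests sub-networks for Gene Ontology enrichment with
    true-path propagation and Fisher's exact test, maps the chromosomal
    expression landscape, and surveys secondary-metabolite gene cluster
    co-expression to rank candidate trans-acting regulators. Includes a
    synthetic-compendium generator with planted co-expression modules,
    ontologies and gene catalogs so every stage can be validated against
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
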