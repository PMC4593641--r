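Package: pathoCNV
Title: Phenotype-Aware Prioritization of Clinically Harmful Copy Number Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-layer classification of copy number variants (CNVs) by
    clinical harmfulness. A gene-level Random Forest is trained on Gene
    Ontology Slim features expanded through a weighted gene interaction
    network (Dijkstra subnetworks with a sink node, random-walk neighbor
    ranking, rank- and evidence-damped feature weights) and on patient
    phenotype indicators, with training instances replicated according to
    an ontology-similarity relevance score between each gene and known
    phenotype-causing genes. The per-gene causative calls are then combined
    with CNV length and overlap frequency against benign variant catalogs
    (DGV-style study sets) in a Naive Bayes CNV classifier. Includes
    information-content semantic similarity over OBO taxonomies, readers
    for OBO/GAF/BED/edge-list formats, balanced and patient-based
    evaluation protocols, and a synthetic cohort generator with a
    plantable function-to-harmfulness signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    randomForest,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
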