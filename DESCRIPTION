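Package: idphenomics
Title: Integrative Phenomics of an Intellectual-Disability Gene Screen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the integrative analysis of a Drosophila RNAi screen
    of intellectual-disability (ID) gene orthologs: phototaxis index
    quantification and hit calling, aggregation of per-line phenotype
    annotations into per-gene phenotype profiles and major classes,
    rank-based tissue-of-highest-expression assignment from EST-style
    expression matrices, permutation-based interaction-network enrichment
    (uniform and degree-matched nulls), extraction of homotypic
    phenotype modules as connected components, and ontology-based human
    phenotype-similarity scoring with weighted feature vectors, recursive
    ancestor augmentation, subtree exclusion and empirical null
    distributions. Includes seeded synthetic-data generators that emulate
    the statistical structure of the real inputs (sparse interaction
    networks with planted modules, rooted DAG ontologies with a designated
    excludable subtree, group-coherent term annotations, spiked expression
    matrices) so that every stage can be exercised and validated end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
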