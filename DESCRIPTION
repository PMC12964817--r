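Package: panloc
Title: Local Pangenome Analysis of Structural Variants from Assembly
    Projections and Graph Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing a structural variant inside a local
    pangenome: projection of reference intervals onto assembly contigs
    from PAF alignments with admission filters, a variation-graph data
    model with per-node path depth and core/variable/private
    classification, detection and extraction of differential subregions,
    per-node read coverage from graph alignments (GAF) with
    depth-and-length normalization and diploid genotype / copy-number
    calling, exact association testing between carrier status and a
    binary phenotype, and a seeded synthetic-data generator producing
    haplotypes, truth graphs, reads and alignments with known genotypes
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
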