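Package: funcmodules
Title: Functional Gene Modules from Ontology Semantic Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates gene sets ("functional modules") for gene set
    enrichment analysis from flat-file annotation data. Parses an ontology
    (OBO) and gene association files (GAF) from one or more taxa, builds the
    aspect-restricted annotated term DAG, weights parent-child edges by
    differences in information content, solves all-pairs shortest paths to
    obtain term-term semantic distances, maps those to a gene-gene distance
    matrix, and partitions the gene space by spectral clustering. Modules can
    be exported in GMT format, extended to assembled transcripts via BLAST
    best hits, and visualised as annotated gene-term networks. A synthetic
    data generator with planted module structure supports end-to-end
    benchmarking without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    cluster,
    parallel,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    xml2
Config/testthat/edition: 3
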