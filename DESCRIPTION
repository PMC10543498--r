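Package: scMicrobeAtlas
Title: Reference-Free Atlasing of Single-Microbe Barcode Groups
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for droplet-based single-microbe shotgun sequencing data in
    which reads are grouped by corrected cell barcodes. Implements barcode
    extraction and Hamming-distance-1 correction, a self-contained canonical
    k-mer LCA read classifier with Bracken-style redistribution of counts to a
    target taxonomic rank, the Taxonomic Discovery Algorithm (per-barcode genus
    abundance vectors, purity and classified-fraction filtering, UMAP embedding
    and Leiden clustering, dominant-taxon annotation), integration of
    metagenomic contig read groups as pseudo-barcodes, per-barcode strain
    abundance estimation by variational Bayes over multi-mapping alignment
    likelihoods, and cluster-level analytics (read pooling, coverage and
    rarefaction, error rates, gene presence/absence subclustering, MAPQ-filtered
    reads-per-million feature counting, droplet occupancy arithmetic). A
    synthetic barcode-group simulator with full per-read truth tables makes the
    whole pipeline testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    uwot,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
biocViews: SingleCell, Metagenomics, Microbiome, Classification, Clustering
RoxygenNote: 7.3.3
Collate:
    'scMicrobeAtlas-package.R'
    'RcppExports.R'
    'taxonomy.R'
    'reference.R'
    'barcode-group.R'
    'simulate.R'
    'demux.R'
    'classifier.R'
    'tda.R'
    'strain.R'
    'analytics.R'
    'pipeline.R'
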