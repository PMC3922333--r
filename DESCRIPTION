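Package: gbsmap
Title: Genotyping-by-Sequencing Pipeline for Biparental Mapping Populations
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A complete two-enzyme genotyping-by-sequencing (GBS) analysis
    pipeline for recombinant inbred line (RIL) populations: construction of
    fixed-length restriction-site reference tags from genome assemblies,
    inline-barcode demultiplexing and read standardisation, unique
    one-mismatch read mapping, SNP discovery with a staged filter cascade,
    proportion-rule genotype calling, genetic linkage map construction
    (independence-LOD grouping, marker ordering, Haldane-Waddington
    corrected distances), and QTL interval mapping with permutation
    thresholds, cofactor-adjusted scans and joint multi-locus models.
    Includes a seeded simulator of a barley-style F11 single-seed-descent
    GBS experiment (parental genomes, RIL meiosis, phenotypes, barcoded
    reads) with full truth tables, so the pipeline can be exercised
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, Sequencing, Alignment, QualityControl
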