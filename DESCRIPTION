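Package: mitopool
Title: Pool Design, Read Simulation and Sequence-as-Tag Demultiplexing
    for Multiplex Mitogenome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for tag-free multiplex sequencing of
    complete animal mitochondrial genomes. Screens candidate specimens
    with sliding-window p-distance profiles and the Folmer COI barcode
    proxy, builds maximal compatible sequencing pools under pairwise
    divergence thresholds, estimates per-run capacity and cost for
    common bench-top sequencers, simulates reads from pooled circular
    genomes with a substitution/indel error model and full truth
    tracking, assembles them with a deterministic de Bruijn unitig
    baseline, and demultiplexes the resulting contigs by k-mer
    comparison against a reference marker database, reporting
    per-genome contig overlap summaries. A synthetic mitogenome-family
    generator with region-specific substitution rates provides
    controlled test inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    GenomicRanges
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
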