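Package: phagecomp
Title: Comparative Genomics and Ecology of Bacteriophages
Version: 0.1.0
Authors@R:
    person("phagecomp", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of bacteriophage genomes and
    their ecology in microbial communities. Implements gene-sharing
    similarity (Jaccard index over per-genome ortholog-group sets) with
    reference-anchored clustering and core/exclusive ortholog-group
    queries; synonymous codon-usage statistics for phage and host coding
    sequences with a random-usage baseline, tRNA anticodon-complement
    analysis and target-codon gene ranking; window-based GC profiling,
    genome composition summaries and intergenic-region detection; and
    genome-size-normalized relative-abundance time series with local
    similarity analysis (rank-normalized, delay-bounded dynamic
    programming with permutation significance). Seeded synthetic-data
    generators emit every input format the pipeline consumes, so the
    full analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
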