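Package: bacpool
Title: Post-Assembly Analytics for Pooled-BAC Sequencing Projects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quality assessment of assemblies built from pooled
    BAC (bacterial artificial chromosome) clones: assignment of contigs and
    scaffolds to BAC clones using genetic markers, BAC-end sequences and
    cloning-vector junction detection; insert-size-constrained
    superscaffolding; assembly summary statistics (N50, N-gap accounting,
    GC content, coverage); a reference-versus-assembly discrepancy census
    centred on homopolymer and dinucleotide tandem-repeat length errors;
    microsatellite, gene-model and transposon content summaries; and a
    relative microsynteny quality statistic with tandem-duplication
    collapsing. A synthetic-data generator produces toy genomes, BAC pools
    with BamHI cloning junctions, fragmented scaffolds and diverged
    syntenic region pairs so that every stage can be exercised against
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
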