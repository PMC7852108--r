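Package: viroscan
Title: Group-Aware Random-Forest Detection of Viral Contigs and Proviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies viral sequences in assembled (meta)genomic contigs using
    one random-forest classifier per major viral group (dsDNA phage, NCLDV, RNA,
    ssDNA, virophage), each trained on 27 gene-level genomic features: hallmark
    gene count, annotation-category fractions, gene architecture (size, density,
    overlap, strand switching), start-codon usage, GC statistics, and
    ribosome-binding-site motif composition. Fully viral contigs are found by
    full-sequence scoring with host-edge trimming; integrated proviruses by a
    gene-stepped sliding-window scan with cross-classifier overlap resolution.
    Includes balanced training-set construction from fragmented genomes, a
    seeded synthetic-data generator emulating group-specific annotation
    statistics, and benchmark evaluation (precision, recall, F1, provirus
    recovery, false-positive rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ranger,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
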