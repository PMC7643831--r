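Package: phagefit
Title: Fitness Scoring of Barcoded Transposon Mutant Libraries Under
    Phage Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled barcoded transposon insertion (RB-TnSeq /
    BarSeq) screens in which a mutant library is challenged with a lytic
    bacteriophage. Extracts barcodes from amplicon reads, counts and
    normalizes them to reads per million, pools insertions by gene,
    computes per-gene enrichment and log2 fitness scores, and calls
    significance against a bootstrapped 3-standard-deviation threshold.
    Also provides codon-adaptation analyses of phage genomes against
    candidate hosts (codon usage profiles, enrichment of codons matched
    by phage-encoded tRNA genes, codon usage correlation) and seeded
    synthetic-data generators for libraries, amplicon reads and coding
    sequences so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
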