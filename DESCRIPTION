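Package: mirSeedScan
Title: Genome-Wide Discovery of Conserved miRNA Seed Sites from
    Multi-Species Conservation Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects candidate miRNA seeds from phylogenetic conservation
    signal in prokaryote-style short 3'UTRs. Defines an 80-nt 3'UTR
    downstream of every annotated gene, slides a 7-nt window at 1-nt steps,
    scores each window by its mean per-base conservation (the Window
    Conservation Score), splits windows at each species' median score
    (CS50), and calls a 7-mer a candidate seed when its pooled
    high-conservation window count exceeds the low count under a one-tailed
    binomial test with Bonferroni correction. Includes an exact
    hypergeometric test for the overlap of two seed sets over the 4^7 = 16384
    7-mer universe, CS95-gated target-site and target-gene extraction with
    coding-region exclusion, and a reproducible multi-species genome
    simulator that plants conserved seed sites with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
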