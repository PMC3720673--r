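Package: mirsurvey
Title: Homology-Based Discovery of Conserved Plant miRNAs in Genomic Survey Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable toolkit for homology-based prediction of
    conserved plant microRNAs in genomic survey sequence reads (for example
    454-style chromosome survey sequencing). Known mature miRNAs are located
    on reads by mismatch-bounded, seed-accelerated full-length matching on
    both strands; candidate precursors are validated by folding the read with
    a deterministic nearest-neighbor minimum-free-energy engine, locating the
    mature:star duplex, and applying structural criteria (duplex mismatch cap,
    single-arm placement, multibranch-loop exclusion, minimal folding
    free-energy index). Downstream utilities provide per-family representation
    counting with identical-locus deduplication, descriptive statistics,
    repeat-overlap classification from RepeatMasker-style annotation tables,
    and EST/protein evidence filtering. A seeded synthetic-data generator
    produces reads, precursors, decoys and annotation tables with full ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
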