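Package: haplotagr
Title: Local Read Haplotagging for Long-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns haplotags (HP/PS auxiliary tags) to long sequencing
    reads by approximate local phasing. Putative heterozygous sites are
    detected from alignment pileups, an allele graph is built per 25 kb
    chunk, a dynamic program over consecutive-site allele pairs assigns
    phase-1/phase-2 labels to alleles, and reads are tagged by majority
    vote over the phased alleles they overlap. Includes a diploid read
    simulator with known truth haplotypes and a switch-aware haplotagging
    accuracy evaluator, so the whole pipeline is testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    generics,
    readr,
    jsonlite,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
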