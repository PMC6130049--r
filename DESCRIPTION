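Package: ends3p
Title: Quantification of Polyadenylated and Non-Polyadenylated RNA 3' Ends
    from Metabolic-Labeling 3' End Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-nucleotide RNA 3'-end sequencing of total and
    4-thiouracil (4tU) labeled RNA fractions with and without in vitro
    E-PAP tailing. Extracts RNA 3'-end positions from alignments, masks
    genomic A-rich internal-priming artifacts, normalizes libraries to
    spike-ins by median-of-ratios size factors, subtracts mock-IP
    background, derives non-polyadenylated (pA-) signal by subtracting
    pA+ from pA+,- tracks, quantifies nascent transcription (gene-body
    pA- density) and RNA levels (gene-end pA+ signal), estimates RNA
    decay rates by first-order labeling kinetics and by
    transcription-to-level ratios, classifies splice-junction reads, and
    builds metagene signal matrices. Includes a seeded kinetic simulator
    that generates genomes, annotations, expected signals, Poisson count
    tracks and spliced/unspliced reads with ground-truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite,
    Rsamtools,
    ape
Config/testthat/edition: 3
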