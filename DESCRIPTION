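Package: termpart
Title: Terminator Part Selection and Transgene-Stability Screen Analytics
    for Chlamydomonas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining transcriptional terminator (3' UTR) parts from
    the Chlamydomonas reinhardtii genome annotation and for analysing the
    plate-based screens used to compare them. Covers annotation feature-size
    and intergenic-distance statistics from GFF3 gene models, diurnal FPKM
    expression ranking, UGUAA polyadenylation-motif scanning, Golden Gate
    (MoClo) part domestication and assembly simulation, plasmid-linearization
    flank computation, and the quantitative analytics of multi-subculture
    antibiotic/reporter screens (transformation efficiency with SEM,
    stability curves, GFP-positive fractions, exact and approximate
    two-tailed Mann-Whitney U tests). A synthetic-data module generates
    genomes, expression matrices and stochastic screen outcomes with known
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
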