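Package: ygscan
Title: Sex-Chromosome System Identification by Dual K-mer Genome Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies sex-limited (Y or W) scaffolds in a mixed-sex draft
    genome assembly by comparing each scaffold's single-copy canonical k-mers
    against short reads sequenced separately from males and females. Running
    the scan against both sexes' reads yields two per-scaffold unmatched
    percentages whose joint pattern distinguishes male (XY) from female (ZW)
    heterogamety; an explicit dominance rule turns the two candidate summaries
    into an XY/ZW/inconclusive verdict. Includes a seeded simulator of
    sex-chromosome genomes and error-prone short reads for end-to-end
    validation, per-scaffold TSV/histogram/FASTA exports, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
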