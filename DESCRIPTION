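Package: isomiRpipe
Title: Small RNA-Seq Preprocessing, Template isomiR Classification and
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for bulk small RNA sequencing of miRNAs
    and their template length variants (isomiRs). Implements per-base Phred
    quality filtering, 3' adapter detection and trimming, length and
    ambiguity filtering, collapsing of reads to unique tags, exact-match
    annotation against a miRBase-style mature/hairpin reference, template
    isomiR classification (5'/3' additions and deletions read off the
    hairpin), seed extraction and seed-family aggregation, expression
    filtering, trimmed-mean-of-M-values normalization, two-group
    negative-binomial exact tests with Benjamini-Hochberg correction,
    Pearson-distance hierarchical clustering and a Self-Organizing Tree
    Algorithm (SOTA) for expression profiles, canonical seed-match target
    scanning of 3'UTRs (6mer/7mer-A1/7mer-m8/8mer), and a ground-truthed
    synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
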