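Package: txpconcord
Title: Transcript-Protein Presence Concordance from RNA-Seq and Antibody Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare transcriptome and proteome presence calls in a
    cell line. Quantifies gene expression from uniquely mapped short reads
    using a mismatch clear-zone uniqueness filter, exon-containment read
    assignment and RPKM; derives protein presence calls from antibody-based
    immunohistochemistry (IHC) and immunofluorescence (IF) annotations with
    Western-blot validation categories; and computes the joint three-platform
    concordance statistics: Venn partitions, overlap summaries, chi-square
    association, one-sided Kolmogorov-Smirnov comparisons of expression
    distributions, quantile-binned detection-rate curves, permutation KS
    tests on ordinal validation scores, and hypergeometric gene-set
    over-representation. A synthetic-data generator emulates every input so
    the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
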