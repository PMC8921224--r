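Package: methdose
Title: Methylome Classification, Dosage-Dependent Expression, and
    Split-Read Transposon Insertion Calling for Methyltransferase
    Mutant Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for genotype panels in which DNA
    methyltransferases have been knocked out singly and in combination
    (wild type, a non-CG-deficient quadruple mutant, a CG-deficient
    single mutant, and a methylation-free quintuple mutant).  Provides
    per-cytosine bisulfite methylome handling (context assignment,
    coverage filtering, weighted methylation levels, windowed profiles,
    non-conversion estimation from an unmethylated organelle control),
    a one-tailed binomial classifier that assigns expressed genes to
    six methylation categories (gbM, Intron-teM, Other-teM, pM, dM,
    UM), negative-binomial differential expression with cross-genotype
    dosage/redundancy pattern classification, an intron-methylation
    3'-transcript ratio test, split-read detection of non-reference
    transposon insertions with target-site-duplication calling, and a
    synthetic-data generator that plants ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
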