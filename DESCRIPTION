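Package: splicetriplet
Title: Exon-Triplet Splicing Quantification and Splicing-Modulator
    Response Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies drug-induced differential splicing of exon triplets
    from splice-junction read counts (percent spliced-in, stratified
    Cochran-Mantel-Haenszel testing across paired replicates,
    Benjamini-Hochberg FDR, response classification), trains a small
    convolutional neural network on one-hot encoded splice-junction flank
    sequence to predict treatment response (inclusion, exclusion, unchanged),
    interprets the trained model (first-layer filter motifs, filter ablation,
    positional importance, in silico saturation mutagenesis, 5-mer
    enrichment), and triages splice-disrupting pathogenic variants predicted
    to be rescued by a splicing modulator compound. Includes a synthetic-data
    generator emulating the paired treated/control fibroblast design so the
    whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
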