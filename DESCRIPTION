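Package: photoclose
Title: Comparative Open-Chromatin Analysis of Rod and Cone Photoreceptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative ATAC-seq analysis of purified photoreceptor
    populations: construction and classification of a cross-sample peak atlas,
    genome-wide chromatin-closure quantification via fixed-window coverage
    ECDFs, a median-of-ratios normalized negative-binomial differential test
    for accessibility and expression, a motif-grammar engine (PWM scanning,
    composition-matched backgrounds, redundancy collapse, co-occurrence and
    spacing statistics), exact k-mer analysis of homeodomain dimer
    configurations in reporter libraries, and integration of accessibility
    with gene expression. A parameterized simulator generates complete
    synthetic inputs (genome, peaks, fragments, counts, motifs, reporter
    library) with planted ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
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
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, ATACSeq, Sequencing, MotifAnnotation,
    DifferentialPeakCalling, GeneRegulation
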