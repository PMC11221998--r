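Package: shallowNIPT
Title: Shallow Whole-Genome Sequencing Analysis for Noninvasive Prenatal Testing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for noninvasive prenatal testing (NIPT) from shallow
    whole-genome sequencing of maternal plasma cell-free DNA. Implements
    binned read counting from alignments, GC-bias correction, reference-panel
    normalization (per-bin and per-chromosome z-scores), dual-method autosomal
    aneuploidy calling with a consensus rule, fetal sex determination by two
    chromosome-Y statistics, sex-chromosome aneuploidy classification,
    fetal-fraction estimation (chrY scaling and elastic-net regression),
    sub-chromosomal copy-number segment detection on log2 ratios, circos-style
    track export, and a negative-binomial cfDNA cohort simulator so that every
    stage is testable without external data.
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
    Rsamtools,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CopyNumberVariation, Coverage, Sequencing, Genetics
RoxygenNote: 7.3.3
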