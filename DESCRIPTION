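Package: c4recruit
Title: Cross-Species Discovery of Candidate Recruited Cis-Regulatory Motifs
    in C4 Photosynthesis Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying short DNA motifs that may have been
    recruited into C4 photosynthesis genes from co-expressed
    non-photosynthetic genes, by comparing a C4 species (e.g. maize)
    with a C3 relative (e.g. rice). The package clusters time-series
    expression profiles (spline/polynomial smoothing, SD normalization,
    k-means with a figure-of-merit diagnostic), reconciles multiple
    ortholog call-sets into one-to-one pairs, extracts five genomic
    segment classes per gene (promoter, 5'UTR, 3'UTR, CDS, intron),
    discovers enriched motifs with three independent engines (ZOOPS EM,
    exhaustive word enumeration, and biophysical PWM-library affinity),
    forms cross-method/cross-k/cross-species consensus motif sets by
    PWM alignment with an empirical match p-value, classifies
    cross-species expression-pattern relationships by distance, rank
    correlation and normalized mutual information, and calls candidate
    recruited motifs. A fully specified synthetic two-species benchmark
    generator with planted ground truth makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
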