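Package: cnvpop
Title: Population-Scale Copy Number Variant Detection from Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and genotypes copy number variation regions (CNVRs)
    across populations of resequenced individuals from per-window read
    depth. Implements overlapping sliding-window depth extraction with gap
    filtering, absolute copy number correction over duplicated windows
    (>=97 percent sequence similarity), per-sample GC-bias correction, sex
    chromosome ploidy adjustment, median normalization, multi-criteria
    population CNVR discovery (individual depth thresholds, allele
    frequency, adjacent-window correlation), Gaussian-mixture genotyping
    with Dirichlet-process component inference, and VCF output. Includes a
    synthetic population simulator (segmental duplications, deletions,
    duplications, trios) and callset evaluation metrics (reciprocal
    overlap sensitivity, Mendelian inconsistency, genotype concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    S4Vectors,
    cluster,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
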