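Package: aneuscreen
Title: Shallow Whole-Genome Sequencing Aneuploidy Screening with an
    Ensemble of Chromosome-Dosage Z Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Non-invasive prenatal testing (NIPT) caller for autosomal
    trisomies 13, 18 and 21 from shallow whole-genome sequencing bin
    counts. Implements 50 kb bin counting from coordinate-sorted
    alignments, GC-content correction, chi-squared based variation
    reduction against a euploid reference cohort, and three
    chromosome-dosage statistics: the standard Z-score (STD), the
    normalized chromosome value (NCV) with denominator-set selection,
    and the within-sample reference bin (WSRB) statistic. The three Z
    statistics are combined by a logistic-regression ensemble evaluated
    with leave-one-out cross-validation. A negative-binomial cohort
    simulator with GC bias, overdispersed bins and fetal-fraction
    trisomy spike-ins makes the full stack testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, Coverage, Sequencing, Classification
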