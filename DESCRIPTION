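Package: epicross
Title: Cross-Species Conservation Analysis of Regulatory Epigenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing regulatory-element landscapes between two
    genomes related by a pairwise alignment chain, motivated by comparative
    ChIP-seq studies of regulatory and conventional CD4+ T cells. Implements
    a UCSC chain parser and liftOver-style interval mapping with an
    iterative center-outward sub-interval orthology search, construction of
    a cross-species union atlas of regulatory elements, strand-shifted read
    pileup and RPM quantification with peak filters, lineage-specificity
    classification and overlap-enrichment statistics, binding-site
    conservation and motif enrichment, polymorphism-constraint permutation
    tests over DNase hypersensitive sites, allele-specific histone
    acetylation calling (exact binomial imbalance, LD collapsing, Fisher
    aggregation against an empirical null, zygosity-normalized genotype
    regression), disease-SNP enrichment, and synthetic-data generators that
    plant ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings
Suggests:
    VariantAnnotation,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
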