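Package: cfFragmentomics
Title: Cell-Free DNA Fragmentomics, Xenograft Read Deconvolution and
    ctDNA Fraction Estimation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for liquid-biopsy fragmentomics built around a
    two-genome (graft tumor / host normal) xenograft design: a synthetic
    paired-end cfDNA alignment simulator with nucleosomal-ladder and
    gamma fragment-length models, fragment extraction and size profiling
    from SAM/BAM, sub-nucleosomal ladder periodicity detection,
    graft/host/ambiguous read-pair classification, variant-allele-
    frequency based circulating-tumor-DNA fraction estimation with
    bootstrap intervals, 5 kb bin copy-gain rank-sum testing, and cohort
    statistics linking mitochondrial cfDNA fragment length to tumor
    burden.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, Coverage, CopyNumberVariation, Software
RoxygenNote: 7.3.3
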