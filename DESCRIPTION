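Package: popsweep
Title: Domestication Sweep Scans and Population Genomics from
    Transcriptome-Derived SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population-genomic analysis of crop domestication from
    transcriptome-derived SNPs in a wild progenitor and a cultivated
    population: read-support and allele-frequency genotype filters,
    codon-degeneracy site annotation, nucleotide diversity (pi) and
    Weir-Cockerham FST in sliding windows, linkage-disequilibrium decay
    with an exact Hardy-Weinberg filter, a cross-population
    composite-likelihood (XP-CLR-style) selective-sweep scan with
    quantile region calling and a pi-ratio cross-filter, and
    principal-component-adjusted association for a quantitative bolting
    phenotype.  A Balding-Nichols two-population simulator with planted
    sweeps, read-depth genotype evidence and a causal phenotype SNP
    provides fully synthetic inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Genetics, SNP, PopulationGenetics, Sequencing
RoxygenNote: 7.3.3
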