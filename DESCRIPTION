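Package: PanelImpute
Title: Low-Density SNP Panel Design and Genotype Imputation Benchmarking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained workbench for designing low-density SNP
    genotyping panels and benchmarking genotype imputation accuracy in
    livestock populations. Provides PLINK PED/MAP and minimal VCF input,
    SNP- and sample-level quality control (call rate, GenCall-style
    quality, Hardy-Weinberg equilibrium, heterozygosity outliers,
    duplicate and parentage checks), design of custom low-density panels
    by minor allele frequency, linkage disequilibrium and physical
    spacing criteria, a pedigree-aware gene-dropping genotype simulator
    with crossbred population structure, deterministic family- and
    population-based reference imputation engines (Mendelian fill-in,
    ungenotyped-parent inference from offspring, overlapping
    sliding-window haplotype matching, one- and two-step strategies),
    and masking-based evaluation by concordance rate and allelic
    R-squared with per-animal, per-SNP, per-chromosome and
    MAF-class stratifications.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: SNP, Genetics, QualityControl, Software
RoxygenNote: 7.3.3
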