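Package: exposeQTL
Title: Discovery of Exposure-Dependent cis-Regulatory Variants from Paired
    Expression, Allele-Specific Read Counts and Population Allele Frequencies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to map gene-by-environment (GxE) cis-regulatory variants
    from paired-condition transcriptome studies. Implements a
    between-condition effect-size test on Fisher z-transformed eQTL
    correlations, gene-level phased allele-specific expression (ASE) with
    read-depth and mono-allelic filters, a differential-ASE test restricted
    to eQTL heterozygotes, directional-concordance rules and a combined
    false-discovery procedure, within-individual fold-change response-eQTL
    (reQTL) mapping with permutation null distributions, and an
    environmental allele-frequency association stage with background-based
    empirical p-values. A synthetic-data module generates genotype,
    paired-condition expression, allele-specific count and population
    allele-frequency datasets with the statistical structure the analysis
    assumes, so that every stage can be exercised and calibrated without
    access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, SNP, GeneticVariability, Transcriptomics,
    StatisticalMethod
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'ase.R'
    'combine.R'
    'eqtl.R'
    'simulate.R'
    'calibration.R'
    'env.R'
    'exposeQTL-package.R'
    'io.R'
    'vcf.R'
    'pipeline.R'
    'reqtl.R'
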