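Package: mirmednet
Title: Integrative miRNA Network Analysis for Chronic Lung Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for integrative small-RNA
    analysis in chronic lung disease cohorts: miRNA locus quantification and
    read-length quality control, RPM normalization and empirical-Bayes batch
    adjustment, negative-binomial differential expression with
    likelihood-ratio disease tests, PAM-based consensus clustering of samples
    and miRNAs with cluster-phenotype association models, covariate-adjusted
    eQTL scanning with cis/trans classification, causality-inference-test
    (CIT) construction of condition-specific SNP-miRNA-mRNA mediation
    networks with scale-free checks and differential connectivity, and
    5'-isomiR seed-shift target analysis with preranked GSEA. A synthetic
    cohort generator with known ground truth (Hardy-Weinberg genotypes,
    negative-binomial counts with batch effects, planted mediation triplets,
    5' read-offset distributions) supports validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    cluster,
    sva,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    fgsea,
    optparse,
    vcfR
Config/testthat/edition: 3
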