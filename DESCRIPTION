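Package: altsweep
Title: Breed-Specific Selection Scans for High-Altitude Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to localize breed-specific selective sweeps from SNP-array
    genotypes and to interrogate candidate loci with re-sequencing panels.
    Implements per-locus unbiased Weir-Cockerham pairwise FST, the d_i
    breed-differentiation statistic with empirical p-values and top-quantile
    outlier calling, 500-kb single-linkage merging of significant SNPs into
    sweep regions, Fisher's exact allele-frequency divergence tests with
    gene-model and conserved-element annotation, and an altitude-gradient
    allele-frequency summary. A Balding-Nichols genotype simulator with
    directional-selection injection, PLINK PED/MAP and VCF text I/O, quality
    control, LD pruning and decay, genotype PCA and neighbor-joining trees
    round out a fully testable pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
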