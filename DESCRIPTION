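Package: pines
Title: Phenotype-Informed Scoring of Noncoding Variants from Epigenetic Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes noncoding variants by comparing their binary
    epigenetic annotation profiles (histone marks, DNase hypersensitivity,
    chromatin states, conservation, chromatin interactions) against a genomic
    background. Annotation vectors are projected into a decorrelated space via
    a low-rank eigendecomposition of the background covariance, scored by the
    angle to the maximal-annotation-load direction scaled by the whitened
    vector lengths, and converted to empirical p-values against background
    variants. Annotation weights can be set manually or learned from GWAS lead
    SNPs by allele-frequency-matched enrichment resampling. Includes
    simulators for correlated binary annotation matrices and toy genomic
    fixtures, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    mvtnorm,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC,
    jsonlite
Config/testthat/edition: 3
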