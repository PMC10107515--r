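Package: crossploidy
Title: Inference of Cross-Ploidy Hybridization and Gene Flow in Contact Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether two co-occurring plant populations that
    differ in ploidy hybridize in a contact zone. Implements the full inference
    chain from a biallelic SNP genotype matrix and a marker-sequence alignment:
    missingness and linkage filtering, Weir-Cockerham F_ST, analysis of
    molecular variance (AMOVA) with permutation testing, mean-imputed principal
    component analysis, K = 2 admixture-proportion estimation with bootstrap
    intervals, six-category hybrid-class posterior assignment, and joint
    site-frequency-spectrum demographic inference under four
    isolation-with-migration models with fixed inbreeding, compared by AIC over
    subsampled replicates. Includes a structured-coalescent simulator of
    two-population secondary-contact data with known truth for power and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    ape,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
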