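Package: ucepopgen
Title: Two-Population Divergence Genomics with Ultraconserved Element Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of two recently diverged
    populations genotyped at multi-SNP sequence loci such as ultraconserved
    elements (UCEs). Includes a structured-coalescent simulator for six
    standard two-population divergence models, diversity and differentiation
    statistics (nucleotide diversity, dxy, dA, Weir-Cockerham FST with a
    permutation G-test, exact Hardy-Weinberg tests, heterozygosity summaries,
    PCA/LDA population assignment), four-gamete recombination filtering,
    folded joint site-frequency-spectrum construction with block-jackknife
    replicates, Poisson composite-likelihood demographic model fitting by
    Monte-Carlo coalescent expectation, and conversion of diffusion-scaled
    parameters into effective population sizes, years, and migrants per
    generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
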