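Package: paleocanid
Title: Ancient-DNA Damage-Aware Genotyping, f-Statistics, Coalescent
    Divergence Dating and Copy-Number Estimation for Canid Paleogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for desk-scale paleogenomic analysis of ancient canid
    genomes: simulation of coalescent genotype panels, damaged ancient-DNA
    read stacks and read-depth tracks; tabulation and Weibull-decay fitting
    of post-mortem deamination damage; damage-aware genotype likelihoods
    and calling with depth and genotype-quality filters; f2/f3/f4/D
    statistics with weighted block jackknife, f4-ratio admixture estimation
    and expected-f evaluation/fitting on user-specified admixture graphs; a
    coalescent derived-allele-sharing estimator of population divergence
    time with mutation-rate calibration from sample age; GC-corrected
    read-depth copy-number estimation; and neighbour-joining trees with
    genomic-window bootstrap plus dog/wolf haplotype classification at
    candidate loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    ape,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
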