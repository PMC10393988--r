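Package: paleokin
Title: Kinship, Pedigree and Admixture Inference for Low-Coverage Ancient Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for population-genetic and kinship analysis of
    low-coverage ancient DNA. Provides damage-aware genotype-likelihood calling and
    pseudo-haploid calling from read pileups, genetic-sex assignment from sex-chromosome
    read ratios, pairwise relatedness estimation from pseudo-haploid mismatch rates
    (READ-style) and from genotype likelihoods (maximum-likelihood k-coefficients,
    KING-robust theta, R0/R1), X-chromosome kinship, a rule-based pedigree
    reconstruction engine driven by uniparental markers and age classes, f3/f4/D
    statistics with weighted block jackknife on autosomes and the X chromosome,
    qpAdm-style admixture-proportion estimation with nested-model and
    rotating-outgroup logic, and Y-chromosome haplogroup assignment against an
    ISOGG-style branch-SNP tree. A synthetic-data module simulates multi-population
    allele frequencies on admixture graphs, multigenerational pedigrees with
    Mendelian autosomal, X-linked, Y and mitochondrial transmission, and damaged
    low-coverage sequencing reads, so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
Config/testthat/edition: 3
RoxygenNote: 7.3.3
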