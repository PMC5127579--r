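Package: strscape
Title: Spatially Explicit Analysis of Forensic STR Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for geographic analysis of multi-allelic short tandem
    repeat (STR) genotype surveys: Genepop input/output with microvariant
    support, classical diversity and fixation statistics (Weir-Cockerham
    F-statistics with permutation tests, Hardy-Weinberg exact Markov chain
    test, EM estimation of null-allele frequencies), spatial principal
    component analysis on k-nearest-neighbour networks with Moran's I,
    squared-loading quantile reduction of allele sets with biallelic dosage
    recoding, Moran correlograms, Mantel tests and ordinary kriging of
    allele-frequency surfaces, and a backward-in-time coalescent simulator
    for split-from-pool demographies used to bound migration rates
    compatible with observed Fst. Includes a synthetic-data generator that
    emulates longitudinal allele-frequency clines, local frequency foci,
    inbreeding and null alleles so the whole pipeline is testable without
    access to confidential genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    geosphere,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
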