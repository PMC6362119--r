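Package: phylogeoABC
Title: Coalescent Simulation and Approximate Bayesian Computation for
    Phylogeographic Model Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing refugial-colonization hypotheses from haploid
    (mtDNA-like) sequence alignments: descriptive population-genetic
    statistics (site classification, haplotype and nucleotide diversity,
    uncorrected p-distances and barcoding-gap partitioning, Watterson and
    pi estimators of theta with conversion to effective population size),
    one-level analysis of molecular variance (AMOVA) with permutation
    testing, statistical-parsimony (TCS-style) haplotype networks with a
    95% connection limit, a fast coalescent simulator of divergence
    demographies with Jukes-Cantor sequence evolution, and DIYABC-style
    approximate Bayesian computation: reference tables of summary
    statistics, model choice by direct rejection and weighted multinomial
    logistic regression, local-linear-regression parameter posteriors, and
    pseudo-observed-dataset validation with type I / type II error
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    nnet
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
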