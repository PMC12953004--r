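Package: crustnet
Title: Community Assembly and Co-Occurrence Network Stability for
    Biocrust Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing microbial community assembly and
    co-occurrence network stability along biological soil crust
    (biocrust) succession.  Implements null-model phylogenetic
    beta-diversity (beta-mean-nearest-taxon distance and its
    standardised effect size, betaNTI) with classification of assembly
    processes into homogeneous selection, variable selection and
    stochasticity; compositionally robust SparCC correlation inference
    with permutation pseudo p-values; co-occurrence network
    construction with within-module (Zi) and among-module (Pi)
    connectivity keystone detection; node-removal robustness and
    global-efficiency vulnerability experiments, including paired
    comparisons of networks with and without a focal taxon group such
    as cyanobacteria; alpha diversity (Shannon, ACE), rarefaction and
    taxon partitioning utilities; and a synthetic-data generator that
    produces phylogenies, stage-structured communities with a known
    selection regime, and compositional count tables with planted
    correlations and planted keystone topology.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    vegan,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
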