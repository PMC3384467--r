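Package: cogevo
Title: COG-Based Evolutionary Attribution of Horizontal Gene Transfer,
    Split Supernetworks, and Polyester Fermentation Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative-genomic analysis of carbohydrate
    transport and metabolism genes in a halophilic bacterium: simulation of
    clusters of orthologous proteins (COGs) with planted horizontal gene
    transfer (HGT) ground truth, maximum-likelihood protein phylogenetics
    under the WAG model with empirical frequencies (complete deletion of
    gaps, ML pairwise distances, neighbor-joining start trees, Felsenstein
    pruning likelihood, NNI hill-climbing), sister-clade donor-category
    attribution of focal alleles with category tallies, metabolic pathway
    polymorphism annotation, Z-closure split supernetworks with
    compatibility diagnostics and NEXUS export, genome occupancy and G+C
    summary statistics, an acidic/basic residue composition screen for
    halophilic character, and batch-culture polyhydroxybutyrate (PHB)
    fermentation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
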