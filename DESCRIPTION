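Package: chromsteer
Title: Hi-C-Constrained Coarse-Grained Modelling of Chromosome Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical selection of significant cis-chromosome Hi-C contacts
    with a zero-inflated negative binomial test and Benjamini-Hochberg control,
    imposition of the selected contacts as steered centre-of-mass restraints on
    a coarse-grained bead-spring polymer model of chromosomes confined in a
    spherical nucleus, and analysis of the resulting conformations: restraint
    satisfaction curves, radial positioning profiles, sequence-continuous
    macrodomain partitions, Procrustes comparison and multidimensional-scaling
    reconstruction. Includes a synthetic-data generator so the whole pipeline
    is testable without external Hi-C data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
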