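Package: gainloss
Title: Gain and Loss of Binary Characters on Phylogenies by
    Expectation-Maximization
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A probabilistic model for the evolution of binary
    (presence/absence) characters, such as introns at individual loci or
    genes in genomes, on a known rooted bifurcating phylogeny.  Each
    branch carries its own gain and loss coefficients, each gene its own
    gain and loss rates, and per-site rate heterogeneity is modelled by a
    zero-inflated unit-mean gamma mixture integrated over a discrete
    category grid.  Parameters are estimated by an expectation-
    maximization algorithm built on Felsenstein pruning with missing
    data, using a two-phase (homogeneous supergene, then per-gene)
    procedure.  The package reconstructs expected ancestral occupancies
    and per-branch gain/loss/retention events, simulates trees, models
    and data sets with full ground-truth logging, and ships a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
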