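Package: syndecay
Title: Synteny Decay, Orthology and Gene-Family Dynamics on Dated Phylogenies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative genomics of gene order on dated phylogenies:
    reciprocal-best-hit orthology from BLAST-style hit tables, detection of
    pairwise syntenic blocks under gap and inversion limits, exponential-decay
    estimates of per-million-year synteny-loss rates, weighted least-squares
    mapping of loss distances onto a fixed dated tree (Fitch-Margoliash with a
    user topology), permutation calibration of consistent gene-family
    expansion and contraction at ancestral nodes, simulation-based
    phylogenetic ANOVA, exact rank and binomial tests, and protein
    isoelectric-point and average-residue-weight calculators.  A
    genome-rearrangement simulator (inversions, translocations, gene gain and
    loss along a dated tree) generates annotations, hit tables, family-count
    matrices and Brownian-motion traits so the whole pipeline can be validated
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    MASS,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
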