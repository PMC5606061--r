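Package: scphylofit
Title: Maximum-Likelihood Tumor Phylogenies from Noisy Single-Cell Genotype Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers rooted binary phylogenies of single tumor cells from
    binary or ternary genotype matrices produced by single-cell DNA
    sequencing. Observed genotypes are modelled as noisy realizations of
    true genotypes through explicit false-positive and allelic-dropout
    (false-negative) error rates, and true genotypes evolve along the tree
    under a finite-sites continuous-time Markov model that allows point
    mutations, loss of heterozygosity, deletions, and back-mutation. Tree,
    error rates and evolution-model parameters are estimated jointly by a
    stochastic heuristic search over tree space with subtree
    prune-and-regraft, nearest-neighbor-interchange and subtree-swap
    proposals. Also provides Felsenstein-pruning likelihood computation,
    error-aware joint maximum-likelihood ancestral genotype reconstruction
    and mutation placement, k-medoids clonal clustering, bipartition-based
    tree-distance metrics, a four-gamete test for infinite-sites
    violations, and a full synthetic-data simulator with doublets,
    per-cell dropout rates and missing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    cluster,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
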