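# Internal fast path: assumes vals columns already ordered as tree$tip.label.
.loglik_engine <- function(tree, vals, alpha, beta, lambda_d, lambda_l, k) {
  cpp_site_logliks(tree$edge, tree$edge.length, vals,
                   length(tree$tip.label), alpha, beta, lambda_d, lambda_l, k)
}

.match_cells <- function(tree, g) {
  miss <- setdiff(tree$tip.label, g$cell_ids)
  if (length(miss)) stop("cells absent from matrix: ", paste(miss, collapse = ", "))
  extra <- setdiff(g$cell_ids, tree$tip.label)
  if (length(extra)) stop("cells absent from tree: ", paste(extra, collapse = ", "))
  g$values[, tree$tip.label, drop = FALSE]
}

#' Log-likelihood of one site under the tree
#'
#' Computes `log L_r(0)`, the probability of the observed genotypes at a
#' single site given the tree, by Felsenstein's pruning algorithm: partial
#' conditional likelihoods are propagated from the leaves (where they equal
#' the error-model observation probabilities) to the root through the
#' genotype transition matrices of each branch, and the root is conditioned
#' on the homozygous reference genotype 0.
#'
#' @param tree A rooted binary `phylo` whose tip labels name the cells.
#' @param column Observed genotypes for the site across cells: an integer
#'   vector (with `NA` for missing) named by cell, or unnamed in
#'   `tree$tip.label` order.
#' @param theta An [error_rates()] object.
#' @param params An [evolution_params()] object.
#' @param mode `"binary"` or `"ternary"`.
#' @return The site log-likelihood (a non-positive number).
#' @export
site_log_likelihood <- function(tree, column, theta, params,
                                mode = c("ternary", "binary")) {
  mode <- match.arg(mode)
  validate_phylo(tree)
  ntip <- length(tree$tip.label)
  if (length(column) != ntip) stop("column length must equal the number of cells")
  if (!is.null(names(column))) {
    miss <- setdiff(tree$tip.label, names(column))
    if (length(miss)) stop("cells absent from column: ", paste(miss, collapse = ", "))
    column <- column[tree$tip.label]
  }
  vals <- matrix(as.integer(column), nrow = 1L)
  k <- length(mode_states(mode))
  as.numeric(.loglik_engine(tree, vals, theta$alpha, theta$beta,
                            params$lambda_d, params$lambda_l, k))
}

#' Total log-likelihood of a genotype matrix
#'
#' Sites evolve independently, so the log-likelihood of the full observed
#' matrix is the sum of per-site log-likelihoods. Missing entries
#' contribute probability 1 (they are marginalized over true genotypes).
#'
#' @param tree A rooted binary `phylo`; tip labels must match the matrix's
#'   cells.
#' @param D A [genotype_matrix()].
#' @inheritParams site_log_likelihood
#' @param per_site Return the vector of per-site log-likelihoods instead of
#'   their sum.
#' @return Total log-likelihood (or per-site vector).
#' @export
total_log_likelihood <- function(tree, D, theta, params, per_site = FALSE) {
  stopifnot(inherits(D, "genotype_matrix"))
  validate_phylo(tree)
  vals <- .match_cells(tree, D)
  k <- length(mode_states(D$mode))
  ll <- .loglik_engine(tree, vals, theta$alpha, theta$beta,
                       params$lambda_d, params$lambda_l, k)
  if (per_site) as.numeric(ll) else sum(ll)
}
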