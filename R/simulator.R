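#' Simulation settings for synthetic single-cell data
#'
#' Bundles every knob of the generative process: a random rooted binary
#' tree on `m` cells, finite-sites evolution of `n` genomic sites along its
#' branches (point mutations, recurrent/back mutations, LOH, multi-locus
#' deletions), doublet formation, FP/FN genotyping noise with per-cell
#' dropout rates, and missing data.
#'
#' Defaults mirror the study conditions used throughout the package's
#' validation experiments: `alpha = 0.01`, `beta_mean = 0.2` with
#' `beta_sd = beta_mean / 10`, and recurrence/LOH/deletion probabilities of
#' 0.05 each.
#'
#' @param m Number of cells (leaves), `>= 4`.
#' @param n Number of genomic sites.
#' @param recur_prob Probability that a drawn mutation event is recurrent
#'   (parallel or back mutation) rather than a fresh mutation.
#' @param loh_prob Per-branch, per-heterozygous-locus probability of loss
#'   of heterozygosity.
#' @param del_prob Per-branch probability of one deletion event affecting a
#'   contiguous run of loci.
#' @param del_length_prob Geometric success probability for the deletion
#'   run length (mean length `1/del_length_prob`).
#' @param doublet_rate Probability that a cell is a doublet.
#' @param alpha False-positive rate.
#' @param beta_mean,beta_sd Mean and standard deviation of the per-cell
#'   false-negative (dropout) rate; default sd is `beta_mean / 10`.
#' @param missing_prob Per-entry missing probability.
#' @param tree_height Target mean root-to-leaf path length (expected
#'   mutations per site accumulated along a lineage).
#' @param mode Output mode, `"ternary"` or `"binary"`.
#' @param seed Optional integer seed for full reproducibility.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(m, n,
                              recur_prob = 0.05, loh_prob = 0.05,
                              del_prob = 0.05, del_length_prob = 0.1,
                              doublet_rate = 0,
                              alpha = 0.01, beta_mean = 0.2,
                              beta_sd = beta_mean / 10,
                              missing_prob = 0,
                              tree_height = 0.5,
                              mode = c("ternary", "binary"),
                              seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(m >= 4, n >= 1, tree_height > 0, del_length_prob > 0,
            beta_sd >= 0)
  probs <- c(recur_prob, loh_prob, del_prob, doublet_rate, alpha,
             beta_mean, missing_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  structure(list(m = as.integer(m), n = as.integer(n),
                 recur_prob = recur_prob, loh_prob = loh_prob,
                 del_prob = del_prob, del_length_prob = del_length_prob,
                 doublet_rate = doublet_rate, alpha = alpha,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 missing_prob = missing_prob, tree_height = tree_height,
                 mode = mode, seed = seed),
            class = "simulation_config")
}

#' Random rooted binary tree on labelled cells
#'
#' Topology is generated by recursively splitting the cell set into two
#' subtrees, the split size uniform on `{1, ..., s - 1}`. Branch lengths
#' are drawn Exponential(rate = m) and rescaled so that the mean
#' root-to-leaf path length equals `height` (branch lengths are expected
#' mutations per site).
#'
#' @param m Number of leaves, `>= 2`.
#' @param height Target mean root-to-leaf path length.
#' @param labels Optional leaf labels (default `cell1..cellm`).
#' @return A `phylo` object.
#' @export
random_binary_tree <- function(m, height = 0.5, labels = NULL) {
  stopifnot(m >= 2)
  if (is.null(labels)) labels <- paste0("cell", seq_len(m))
  stopifnot(length(labels) == m, !anyDuplicated(labels))
  rec <- function(cells) {
    s <- length(cells)
    if (s == 1L) return(cells)
    k <- if (s == 2L) 1L else sample.int(s - 1L, 1L)
    left <- sample(cells, k)
    right <- setdiff(cells, left)
    paste0("(", rec(left), ",", rec(right), ")")
  }
  tree <- parse_newick(paste0(rec(labels), ";"))
  len <- rexp(nrow(tree$edge), rate = m)
  tree$edge.length <- len
  d <- ape::node.depth.edgelength(tree)
  tree$edge.length <- len * height / mean(d[seq_len(m)])
  tree
}

# preorder edge indices (parents before children)
.preorder_edges <- function(tree) {
  kids <- .child_edges(tree)
  ord <- integer(0)
  stack <- .root_node(tree)
  ntip <- length(tree$tip.label)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    es <- kids[[v]]
    ord <- c(ord, es)
    ch <- tree$edge[es, 2]
    stack <- c(stack, ch[ch > ntip])
  }
  ord
}

#' Evolve true genotypes along a tree under the finite-sites model
#'
#' The root carries homozygous reference (0) genotypes at all `n` sites.
#' On each branch of length `t`, a Poisson(`t * n`) number of mutation
#' events occurs. Each event is, with probability `recur_prob`, recurrent:
#' it targets a site already mutated somewhere in the tree, producing a
#' parallel mutation (0 to 1) if the current lineage is unmutated there,
#' or a back-mutation to 0 otherwise. Non-recurrent events mutate a fresh,
#' never-before-mutated site from 0 to 1; when no fresh site remains, all
#' events are recurrent. After mutations, each heterozygous locus
#' independently undergoes LOH with probability `loh_prob` (to 0 or 2,
#' equiprobably), and with probability `del_prob` one deletion hits a
#' contiguous run of loci (geometric length), sending 1 to 0 or 2
#' equiprobably, 2 to 1, and leaving 0 unchanged.
#'
#' @param tree A rooted binary `phylo` with branch lengths.
#' @param config A [simulation_config()] (only the evolution fields are
#'   used).
#' @return List with `G` (the true ternary [genotype_matrix()] of the
#'   leaves) and `ancestral` (an n x (number of nodes) integer matrix of
#'   true states at every node, columns named by cell for tips and
#'   `node<k>` otherwise).
#' @export
evolve_genotypes <- function(tree, config) {
  validate_phylo(tree)
  n <- config$n
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  states <- matrix(0L, nrow = n, ncol = n_nodes)
  mutated_anywhere <- logical(n)
  for (e in .preorder_edges(tree)) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    g <- states[, p]
    t <- tree$edge.length[e]
    n_events <- rpois(1L, t * n)
    for (ev in seq_len(n_events)) {
      fresh <- which(!mutated_anywhere)
      recurrent <- (length(fresh) == 0L) ||
        (runif(1) < config$recur_prob && any(mutated_anywhere))
      if (recurrent) {
        pool <- which(mutated_anywhere)
        if (length(pool) == 0L) next
        s <- pool[sample.int(length(pool), 1L)]
        g[s] <- if (g[s] == 0L) 1L else 0L
      } else {
        s <- fresh[sample.int(length(fresh), 1L)]
        g[s] <- 1L
        mutated_anywhere[s] <- TRUE
      }
    }
    het <- which(g == 1L)
    if (length(het)) {
      hit <- het[runif(length(het)) < config$loh_prob]
      if (length(hit)) g[hit] <- sample(c(0L, 2L), length(hit), replace = TRUE)
    }
    if (runif(1) < config$del_prob) {
      start <- sample.int(n, 1L)
      run <- start:min(n, start + rgeom(1L, config$del_length_prob))
      gs <- g[run]
      het <- run[gs == 1L]
      if (length(het)) g[het] <- sample(c(0L, 2L), length(het), replace = TRUE)
      g[run[gs == 2L]] <- 1L
    }
    states[, v] <- g
  }
  colnames(states) <- c(tree$tip.label, paste0("node", (ntip + 1L):n_nodes))
  rownames(states) <- paste0("site", seq_len(n))
  G <- genotype_matrix(states[, seq_len(ntip), drop = FALSE], mode = "ternary",
                       site_ids = rownames(states), cell_ids = tree$tip.label)
  list(G = G, ancestral = states)
}

#' Doublet genotype merge operator
#'
#' Expected genotype when two cells are co-captured: identical genotypes
#' are preserved (0+0 = 0, 1+1 = 1, 2+2 = 2) and every mixed combination
#' yields a heterozygous call (1). Commutative and idempotent. The same
#' rule collapses correctly to binary data.
#'
#' @param g1,g2 Integer genotype scalars/vectors in \{0, 1, 2\}.
#' @return Merged genotypes.
#' @export
doublet_merge <- function(g1, g2) ifelse(g1 == g2, g1, 1L)

#' Inject doublets into a true genotype matrix
#'
#' Each cell independently becomes a doublet with probability `delta`; its
#' column is merged entrywise (via [doublet_merge()]) with the column of a
#' uniformly chosen other cell.
#'
#' @param G A [genotype_matrix()] without missing entries.
#' @param delta Doublet probability per cell.
#' @return `G` with merged columns; the character vector of doublet cell
#'   ids is attached as attribute `"doublet_cells"`.
#' @export
inject_doublets <- function(G, delta) {
  stopifnot(inherits(G, "genotype_matrix"), delta >= 0, delta <= 1)
  m <- ncol(G$values)
  if (m < 2L) stop("need at least 2 cells to form doublets")
  vals <- G$values
  is_doublet <- runif(m) < delta
  for (j in which(is_doublet)) {
    partner <- sample(setdiff(seq_len(m), j), 1L)
    vals[, j] <- doublet_merge(vals[, j], G$values[, partner])
  }
  out <- genotype_matrix(vals, mode = G$mode, site_ids = G$site_ids,
                         cell_ids = G$cell_ids)
  attr(out, "doublet_cells") <- G$cell_ids[is_doublet]
  out
}

#' Add false-positive and false-negative genotyping errors
#'
#' Draws a per-cell dropout rate `beta_c` from Normal(`beta_mean`,
#' `beta_sd`) truncated to \[0, 1\], then resamples every entry from the
#' error-model conditional Pr(D | G; alpha, beta_c): in ternary mode a true
#' 0 becomes 1 with probability `alpha` and 2 with probability
#' `alpha * beta_c / 2`; a true 1 drops to 0 or 2 with probability
#' `beta_c / 2` each; a true 2 is never altered. In binary mode 0 flips to
#' 1 with probability `alpha` and 1 to 0 with probability `beta_c`.
#'
#' @param G True [genotype_matrix()].
#' @param alpha False-positive rate.
#' @param beta_mean Mean per-cell false-negative rate.
#' @param beta_sd Standard deviation of the per-cell rate (default
#'   `beta_mean / 10`).
#' @return Observed [genotype_matrix()] with the per-cell rates attached
#'   as attribute `"beta_c"` (named numeric vector).
#' @export
add_errors <- function(G, alpha, beta_mean, beta_sd = beta_mean / 10) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- ncol(G$values); n <- nrow(G$values)
  beta_c <- vapply(seq_len(m), function(j) {
    repeat {
      b <- rnorm(1, beta_mean, beta_sd)
      if (b >= 0 && b <= 1) return(b)
    }
  }, numeric(1))
  if (beta_sd == 0) beta_c <- rep(beta_mean, m)
  vals <- G$values
  for (j in seq_len(m)) {
    g <- G$values[, j]
    b <- beta_c[j]
    u <- runif(n)
    d <- g
    if (G$mode == "ternary") {
      i0 <- !is.na(g) & g == 0L
      d[i0] <- ifelse(u[i0] < alpha, 1L,
                      ifelse(u[i0] < alpha + alpha * b / 2, 2L, 0L))
      i1 <- !is.na(g) & g == 1L
      d[i1] <- ifelse(u[i1] < b / 2, 0L, ifelse(u[i1] < b, 2L, 1L))
      # true 2 is unaffected
    } else {
      i0 <- !is.na(g) & g == 0L
      d[i0] <- ifelse(u[i0] < alpha, 1L, 0L)
      i1 <- !is.na(g) & g == 1L
      d[i1] <- ifelse(u[i1] < b, 0L, 1L)
    }
    vals[, j] <- d
  }
  out <- genotype_matrix(vals, mode = G$mode, site_ids = G$site_ids,
                         cell_ids = G$cell_ids)
  attr(out, "beta_c") <- setNames(beta_c, G$cell_ids)
  out
}

#' Mask entries as missing
#'
#' @param D A [genotype_matrix()].
#' @param p Independent per-entry missing probability.
#' @return `D` with masked entries set to `NA`.
#' @export
mask_missing <- function(D, p) {
  stopifnot(inherits(D, "genotype_matrix"), p >= 0, p <= 1)
  vals <- D$values
  vals[matrix(runif(length(vals)) < p, nrow(vals), ncol(vals))] <- NA
  genotype_matrix(vals, mode = D$mode, site_ids = D$site_ids,
                  cell_ids = D$cell_ids)
}

#' Simulate a complete synthetic single-cell dataset
#'
#' Runs the full generative pipeline: random tree, finite-sites genotype
#' evolution, optional binarization, doublet injection, FP/FN noise, and
#' missing-data masking.
#'
#' @param config A [simulation_config()].
#' @return List with `tree` (true `phylo`), `G` (true genotype matrix, in
#'   the requested mode), `ancestral` (true states at all nodes, ternary),
#'   `D` (observed noisy matrix), `beta_c` (per-cell dropout rates),
#'   `doublet_cells`, and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tree <- random_binary_tree(config$m, height = config$tree_height)
  ev <- evolve_genotypes(tree, config)
  G <- ev$G
  if (config$mode == "binary") G <- binarize(G)
  Gd <- inject_doublets(G, config$doublet_rate)
  D <- add_errors(Gd, config$alpha, config$beta_mean, config$beta_sd)
  beta_c <- attr(D, "beta_c")
  D <- mask_missing(D, config$missing_prob)
  list(tree = tree, G = G, ancestral = ev$ancestral, D = D,
       beta_c = beta_c, doublet_cells = attr(Gd, "doublet_cells"),
       config = config)
}
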