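#' Joint maximum-likelihood ancestral genotypes
#'
#' Error-aware extension of the joint ancestral-reconstruction dynamic
#' program of Pupko-style max-product propagation: for every node and every
#' possible parent genotype `g`, the bottom-up pass stores the maximizing
#' genotype `h` (transition probability times subtree partial likelihood;
#' at leaves the observation probability under the error model, 1 for
#' missing data), and the top-down pass fixes the root to genotype 0 and
#' reads off each node's stored maximizer given its parent's decided
#' state. Leaves receive error-corrected (denoised) ML states rather than
#' their raw observations. Exact ties are broken toward the lower genotype
#' index.
#'
#' @param tree A rooted binary `phylo` with branch lengths.
#' @param D A [genotype_matrix()]; cells must match the tree's leaves.
#' @param theta An [error_rates()] object.
#' @param params An [evolution_params()] object.
#' @return Integer matrix (sites x nodes) of decided genotypes; columns are
#'   named by cell for leaves and `node<k>` for internal nodes (the root is
#'   `node<m+1>` and is 0 everywhere).
#' @export
ancestral_states <- function(tree, D, theta, params) {
  stopifnot(inherits(D, "genotype_matrix"))
  validate_phylo(tree)
  vals <- .match_cells(tree, D)
  n <- nrow(vals)
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  k <- length(mode_states(D$mode))
  root <- ntip + 1L

  kids <- .child_edges(tree)
  # postorder node list (children before parents)
  ord <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    ch <- tree$edge[kids[[v]], 2]
    stack <- c(stack, ch[ch > ntip])
  }
  ord <- rev(ord)

  parent_edge <- integer(n_nodes)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  logP <- lapply(seq_len(nrow(tree$edge)), function(e)
    log(cpp_expm(cpp_rate_matrix(tree$edge.length[e], params$lambda_d,
                                 params$lambda_l, k))))

  # bottom-up: L[[v]] is k x n (log partial given parent genotype g),
  # M[[v]] is k x n (maximizing own genotype h, 0-based)
  L <- vector("list", n_nodes); M <- vector("list", n_nodes)
  C <- vector("list", n_nodes)  # sum of children partials, by own genotype h
  # observation log-probabilities by observed value (columns: 0..k-1, NA)
  obs_lp <- cbind(vapply(0:(k - 1L), function(d)
    log(as.numeric(cpp_leaf_partial(d, theta$alpha, theta$beta, k))),
    numeric(k)), rep(0, k))
  for (i in seq_len(ntip)) {
    idx <- vals[, i] + 1L
    idx[is.na(idx)] <- k + 1L
    C[[i]] <- obs_lp[, idx, drop = FALSE]
  }
  decide_node <- function(v) {
    # combine own-genotype scores C[[v]] with the parent edge transition
    lP <- logP[[parent_edge[v]]]
    Lv <- matrix(-Inf, k, n); Mv <- matrix(0L, k, n)
    for (g in seq_len(k)) {
      bestval <- rep(-Inf, n); bestarg <- rep(0L, n)
      for (h in seq_len(k)) {
        sc <- lP[g, h] + C[[v]][h, ]
        better <- sc > bestval
        bestval[better] <- sc[better]
        bestarg[better] <- h - 1L
      }
      Lv[g, ] <- bestval; Mv[g, ] <- bestarg
    }
    L[[v]] <<- Lv; M[[v]] <<- Mv
  }
  for (i in seq_len(ntip)) decide_node(i)
  for (v in ord) {
    if (v <= ntip) next
    ch <- tree$edge[kids[[v]], 2]
    C[[v]] <- L[[ch[1]]] + L[[ch[2]]]
    if (v != root) decide_node(v)
  }

  # top-down: root fixed at 0, each node takes its stored maximizer
  states <- matrix(0L, n, n_nodes)
  for (v in c(rev(ord[ord > ntip]), seq_len(ntip))) {
    if (v == root) next
    p <- tree$edge[parent_edge[v], 1]
    states[, v] <- M[[v]][cbind(states[, p] + 1L, seq_len(n))]
  }
  colnames(states) <- c(tree$tip.label, paste0("node", (ntip + 1L):n_nodes))
  rownames(states) <- D$site_ids
  states
}

#' Place mutations on the branches of the tree
#'
#' A mutation (or loss) is placed on every branch whose endpoint states
#' differ at a site, with the direction of change recorded. The
#' chronological rank of a branch is its edge distance from the root
#' (root-adjacent branches have rank 1); ties share a rank.
#'
#' @param tree A rooted `phylo`.
#' @param states Site-by-node state matrix from [ancestral_states()] (or
#'   the simulator's recorded true states).
#' @return Data frame with columns `branch` (`parent->child` using node or
#'   cell names), `site_id`, `from`, `to`, `chrono_rank`, ordered by rank.
#' @export
place_mutations <- function(tree, states) {
  validate_phylo(tree, binary = FALSE)
  ntip <- length(tree$tip.label)
  node_name <- colnames(states)
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  depth <- ape::node.depth.edgelength(tr)
  out <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    diff_sites <- which(states[, p] != states[, v])
    if (!length(diff_sites)) next
    out[[e]] <- data.frame(
      branch = paste0(node_name[p], "->", node_name[v]),
      site_id = rownames(states)[diff_sites],
      from = states[diff_sites, p],
      to = states[diff_sites, v],
      chrono_rank = depth[v],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    return(data.frame(branch = character(0), site_id = character(0),
                      from = integer(0), to = integer(0),
                      chrono_rank = integer(0), stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res[order(res$chrono_rank, res$branch, res$site_id), , drop = FALSE]
}

#' Cluster cells into clonal subpopulations
#'
#' k-medoids (PAM) clustering on a precomputed cell-to-cell distance
#' matrix (typically tree path distances), with the number of clusters
#' chosen between `k_min` and `k_max` to maximize the mean silhouette
#' width.
#'
#' @param dist Square symmetric distance matrix with zero diagonal, e.g.
#'   from [path_distance_matrix()].
#' @param k_min,k_max Range of cluster counts to evaluate (defaults 2-5).
#' @return List with `labels` (named integer vector), `k_star`, and
#'   `silhouette_scores` (mean silhouette per evaluated k).
#' @export
cluster_cells <- function(dist, k_min = 2L, k_max = 5L) {
  dist <- as.matrix(dist)
  m <- nrow(dist)
  stopifnot(m == ncol(dist), isTRUE(all.equal(dist, t(dist))),
            all(diag(dist) == 0))
  if (m < k_min + 1L) stop("need at least k_min + 1 cells to cluster")
  k_max <- min(k_max, m - 1L)
  ks <- k_min:k_max
  scores <- vapply(ks, function(k) {
    fit <- cluster::pam(stats::as.dist(dist), k, diss = TRUE)
    fit$silinfo$avg.width
  }, numeric(1))
  k_star <- ks[which.max(scores)]
  fit <- cluster::pam(stats::as.dist(dist), k_star, diss = TRUE)
  labels <- fit$clustering
  names(labels) <- rownames(dist)
  list(labels = labels, k_star = k_star,
       silhouette_scores = setNames(scores, paste0("k", ks)))
}
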