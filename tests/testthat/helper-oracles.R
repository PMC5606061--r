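# Independent oracles used across the test suite. These deliberately avoid
# the package's pruning/DP code paths: likelihoods and reconstructions are
# computed by exhaustive enumeration over all genotype assignments, and
# graph quantities by breadth-first search on an adjacency list.

# undirected adjacency list (node -> neighbors with edge weights) of a phylo
.adjacency <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  adj <- replicate(n_nodes, list(nodes = integer(0), w = numeric(0)), simplify = FALSE)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]]$nodes <- c(adj[[a]]$nodes, b); adj[[a]]$w <- c(adj[[a]]$w, w)
    adj[[b]]$nodes <- c(adj[[b]]$nodes, a); adj[[b]]$w <- c(adj[[b]]$w, w)
  }
  adj
}

# all-pairs tip path distances by BFS/DFS accumulation from each tip
oracle_path_distances <- function(tree) {
  ntip <- length(tree$tip.label)
  adj <- .adjacency(tree)
  n_nodes <- length(adj)
  out <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(ntip)) {
    dist <- rep(NA_real_, n_nodes); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]$nodes; w <- adj[[v]]$w
      for (i in seq_along(nb)) {
        if (is.na(dist[nb[i]])) {
          dist[nb[i]] <- dist[v] + w[i]
          queue <- c(queue, nb[i])
        }
      }
    }
    out[s, ] <- dist[seq_len(ntip)]
  }
  out
}

# splits of a tree by explicit edge deletion + component search (unrooted
# view, non-trivial only), as canonical "a|b|c" keys of the block holding
# the alphabetically first label
oracle_splits <- function(tree) {
  labs <- tree$tip.label
  ntip <- length(labs)
  if (ntip < 4) return(character(0))
  anchor <- sort(labs)[1]
  adj <- .adjacency(tree)
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    # component containing b after removing edge (a, b)
    seen <- logical(length(adj)); seen[b] <- TRUE
    queue <- b
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]$nodes) {
        if ((v == b && u == a) || (v == a && u == b)) next  # deleted edge
        if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
      }
    }
    block <- labs[which(seen[seq_len(ntip)])]
    if (length(block) <= 1 || length(block) >= ntip - 1) next
    if (!(anchor %in% block)) block <- setdiff(labs, block)
    keys <- c(keys, paste(sort(block), collapse = "|"))
  }
  sort(unique(keys))
}

# all assignments of states 0..k-1 to the given number of slots
.state_grid <- function(slots, k) {
  as.matrix(expand.grid(rep(list(0:(k - 1)), slots)))
}

# brute-force site likelihood: sum over every genotype assignment to all
# non-root nodes (leaf true genotypes included), root fixed at 0
oracle_site_likelihood <- function(tree, column, theta, params, mode) {
  k <- if (mode == "binary") 2L else 3L
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  if (!is.null(names(column))) column <- column[tree$tip.label]
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_probabilities(tree$edge.length[e], params, mode))
  nonroot <- setdiff(seq_len(n_nodes), root)
  grid <- .state_grid(length(nonroot), k)
  total <- 0
  for (r in seq_len(nrow(grid))) {
    g <- integer(n_nodes); g[nonroot] <- grid[r, ]
    p <- 1
    for (e in seq_len(nrow(tree$edge)))
      p <- p * P[[e]][g[tree$edge[e, 1]] + 1, g[tree$edge[e, 2]] + 1]
    for (j in seq_len(ntip))
      p <- p * observation_probability(column[j], g[j], theta, mode)
    total <- total + p
  }
  total
}

# brute-force joint-ML ancestral assignment (max instead of sum); returns
# the maximizing full state vector (all nodes, root = 0) and its probability
oracle_joint_ml <- function(tree, column, theta, params, mode) {
  k <- if (mode == "binary") 2L else 3L
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  root <- ntip + 1L
  if (!is.null(names(column))) column <- column[tree$tip.label]
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_probabilities(tree$edge.length[e], params, mode))
  nonroot <- setdiff(seq_len(n_nodes), root)
  grid <- .state_grid(length(nonroot), k)
  best_p <- -1; best_g <- NULL
  for (r in seq_len(nrow(grid))) {
    g <- integer(n_nodes); g[nonroot] <- grid[r, ]
    p <- 1
    for (e in seq_len(nrow(tree$edge)))
      p <- p * P[[e]][g[tree$edge[e, 1]] + 1, g[tree$edge[e, 2]] + 1]
    for (j in seq_len(ntip))
      p <- p * observation_probability(column[j], g[j], theta, mode)
    if (p > best_p) { best_p <- p; best_g <- g }
  }
  list(states = best_g, prob = best_p)
}

# a random rooted binary phylo on given labels with iid Uniform lengths
random_test_tree <- function(m, min_len = 0.02, max_len = 0.6) {
  tr <- random_binary_tree(m)
  tr$edge.length <- runif(nrow(tr$edge), min_len, max_len)
  tr
}

# canonical topology key (lengths stripped)
topology_key <- function(tree) {
  tr <- tree
  tr$edge.length <- rep(0, nrow(tr$edge))
  write_newick(tr, precision = 1)
}
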