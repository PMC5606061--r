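# Internal mutable tree representation used by the stochastic search:
# par[v] = parent node id (0 for root), len[v] = length of the branch above
# v (0 for root). Node ids follow ape numbering (tips 1..m, root m+1) and
# never change during moves, so the root id is stable and tip labels map
# directly to genotype-matrix columns.

.tree_to_state <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  par <- integer(n_nodes)
  len <- numeric(n_nodes)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  len[tree$edge[, 2]] <- tree$edge.length
  list(par = par, len = len, ntip = length(tree$tip.label),
       labels = tree$tip.label)
}

.state_to_tree <- function(st) {
  nonroot <- which(st$par != 0L)
  tree <- structure(list(edge = cbind(st$par[nonroot], nonroot),
                         edge.length = st$len[nonroot],
                         tip.label = st$labels,
                         Nnode = length(st$par) - st$ntip),
                    class = "phylo", order = NULL)
  tree
}

# descendants of v (including v)
.subtree_nodes <- function(par, v) {
  n <- length(par)
  inside <- logical(n)
  inside[v] <- TRUE
  queue <- v
  while (length(queue)) {
    kids <- which(par %in% queue)
    kids <- kids[!inside[kids]]
    if (!length(kids)) break
    inside[kids] <- TRUE
    queue <- kids
  }
  which(inside)
}

.children_of <- function(par, v) which(par == v)

.sibling_of <- function(par, v) {
  ch <- .children_of(par, par[v])
  ch[ch != v]
}

#' Branch-length multiplier proposal
#'
#' Every branch length l is replaced by `l * r` with an independent
#' multiplier `r = exp(eta * (u - 0.5))`, `u ~ Uniform[0, 1)`. The log
#' Hastings ratio of this proposal is the sum of the log multipliers.
#' Topology is unchanged; `eta` tunes the proposal scale.
#'
#' @param tree A rooted binary `phylo`.
#' @param eta Non-negative tuning parameter.
#' @return List with `tree` and `log_hastings_ratio`.
#' @export
propose_branch_lengths <- function(tree, eta) {
  stopifnot(eta >= 0)
  ne <- nrow(tree$edge)
  r <- exp(eta * (runif(ne) - 0.5))
  tree$edge.length <- tree$edge.length * r
  list(tree = tree, log_hastings_ratio = sum(log(r)))
}

# -- topology moves on the internal state representation ----------------------

.move_stnni <- function(st) {
  ntip <- st$ntip
  root <- ntip + 1L
  # focal branches are internal in the unrooted sense; a child of the root
  # qualifies only when its sibling is internal too (the two root edges
  # form one unrooted branch)
  internal <- which(seq_along(st$par) > ntip & st$par != 0L)
  internal <- internal[st$par[internal] != root |
                         vapply(internal, function(v)
                           .sibling_of(st$par, v) > ntip, logical(1))]
  if (!length(internal)) return(NULL)
  v <- internal[sample.int(length(internal), 1L)]
  u <- st$par[v]
  ch <- .children_of(st$par, v)
  c1 <- ch[sample.int(2L, 1L)]
  s <- .sibling_of(st$par, v)
  if (u == root) {
    # swap across the unrooted branch v--s: child of v with child of s
    ch2 <- .children_of(st$par, s)
    c2 <- ch2[sample.int(2L, 1L)]
    st$par[c1] <- s
    st$par[c2] <- v
  } else {
    # swap a child of v with v's sibling across the branch u--v
    st$par[c1] <- u
    st$par[s] <- v
  }
  st
}

.move_spr <- function(st, extending = FALSE, extension_prob = 0.8) {
  # prune candidates: v with a grandparent (keeps the root id fixed)
  nonroot <- which(st$par != 0L)
  cand <- nonroot[st$par[st$par[nonroot]] != 0L]
  if (!length(cand)) return(NULL)
  v <- cand[sample.int(length(cand), 1L)]
  p <- st$par[v]
  g <- st$par[p]
  s <- .sibling_of(st$par, v)
  # detach: p dissolves, sibling edge absorbs p's branch
  st$par[s] <- g
  st$len[s] <- st$len[s] + st$len[p]
  st$par[p] <- 0L
  inside <- .subtree_nodes(st$par, v)
  # regraft targets: any remaining branch (node b with a parent), outside v's subtree
  targets <- which(st$par != 0L)
  targets <- setdiff(targets, inside)
  if (!length(targets)) return(NULL)
  if (extending) {
    b <- s
    repeat {
      if (runif(1) >= extension_prob) break
      nb <- c(if (st$par[b] != 0L && st$par[b] %in% targets) st$par[b],
              if (st$par[b] != 0L) .sibling_of(st$par, b),
              .children_of(st$par, b))
      nb <- intersect(nb, targets)
      if (!length(nb)) break
      b <- nb[sample.int(length(nb), 1L)]
    }
  } else {
    b <- targets[sample.int(length(targets), 1L)]
  }
  # re-insert p along the branch above b, at a uniform point
  q <- runif(1)
  st$par[p] <- st$par[b]
  st$len[p] <- q * st$len[b]
  st$par[b] <- p
  st$len[b] <- (1 - q) * st$len[b]
  st$par[v] <- p
  st
}

.move_sts <- function(st, extending = FALSE, extension_prob = 0.8) {
  root <- st$ntip + 1L
  cand <- which(st$par != 0L)
  v1 <- cand[sample.int(length(cand), 1L)]
  in1 <- .subtree_nodes(st$par, v1)
  # eligible partners: disjoint subtrees, not an ancestor, not the sibling
  anc <- integer(0)
  a <- st$par[v1]
  while (a != 0L) { anc <- c(anc, a); a <- st$par[a] }
  elig <- setdiff(cand, c(in1, anc, .sibling_of(st$par, v1)))
  if (!length(elig)) return(NULL)
  if (extending) {
    b <- st$par[v1]
    steps <- 0L
    repeat {
      nb <- c(if (st$par[b] != 0L) st$par[b], .children_of(st$par, b))
      nb <- setdiff(nb, in1)
      if (!length(nb)) break
      b <- nb[sample.int(length(nb), 1L)]
      steps <- steps + 1L
      if (runif(1) >= extension_prob && steps >= 1L) break
    }
    if (!(b %in% elig)) return(NULL)
    v2 <- b
  } else {
    v2 <- elig[sample.int(length(elig), 1L)]
  }
  p1 <- st$par[v1]; p2 <- st$par[v2]
  st$par[v1] <- p2
  st$par[v2] <- p1
  st
}

#' Propose a new tree topology
#'
#' One of five stochastic rearrangements: random subtree prune-and-regraft
#' (`rSPR`), extending SPR (`eSPR`, regraft point found by a random walk
#' that crosses one branch at a time with probability `extension_prob`,
#' favouring local changes), stochastic nearest-neighbor interchange
#' (`stNNI`), random subtree swap (`rSTS`), and extending subtree swap
#' (`eSTS`). All moves preserve the leaf set and return a valid rooted
#' binary tree. Moves are implemented in symmetric variants, so the
#' reported log Hastings ratio is 0; when a move has no eligible branch the
#' tree is returned unchanged with a `skipped` flag.
#'
#' @param tree A rooted binary `phylo` with at least 4 leaves.
#' @param move One of `"rSPR"`, `"eSPR"`, `"stNNI"`, `"rSTS"`, `"eSTS"`.
#' @param extension_prob Extension probability for `eSPR`/`eSTS`.
#' @return List with `tree`, `log_hastings_ratio` (0), and `skipped`.
#' @export
propose_topology <- function(tree, move = c("rSPR", "eSPR", "stNNI", "rSTS", "eSTS"),
                             extension_prob = 0.8) {
  move <- match.arg(move)
  if (length(tree$tip.label) < 4L) stop("topology moves need at least 4 leaves")
  st <- .tree_to_state(tree)
  st2 <- switch(move,
                stNNI = .move_stnni(st),
                rSPR = .move_spr(st, extending = FALSE),
                eSPR = .move_spr(st, extending = TRUE, extension_prob),
                rSTS = .move_sts(st, extending = FALSE),
                eSTS = .move_sts(st, extending = TRUE, extension_prob))
  if (is.null(st2))
    return(list(tree = tree, log_hastings_ratio = 0, skipped = TRUE))
  list(tree = .state_to_tree(st2), log_hastings_ratio = 0, skipped = FALSE)
}

# reflect a real into (0, 1): fold at both boundaries
.reflect01 <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

#' Propose new error rates
#'
#' Each component is drawn from a normal distribution centred on its
#' current value and reflected into (0, 1); reflection keeps the proposal
#' symmetric so the Hastings ratio is 1.
#'
#' @param theta An [error_rates()] object.
#' @param sd Proposal standard deviation.
#' @return A new `error_rates` object.
#' @export
propose_error_rates <- function(theta, sd) {
  stopifnot(sd > 0)
  # rare joint-validity violations (alpha + alpha*beta/2 > 1) are redrawn;
  # unreachable for realistic error rates
  for (i in 1:100) {
    a <- .reflect01(rnorm(1, theta$alpha, sd))
    b <- .reflect01(rnorm(1, theta$beta, sd))
    if (a + a * b / 2 <= 1) return(error_rates(a, b))
  }
  theta
}

#' Propose new evolution-model parameters
#'
#' Each rate is drawn from a normal centred on the current value and
#' reflected at 0 (symmetric proposal).
#'
#' @param params An [evolution_params()] object.
#' @param sd Proposal standard deviation.
#' @return A new `evolution_params` object.
#' @export
propose_evolution_params <- function(params, sd) {
  stopifnot(sd > 0)
  evolution_params(abs(rnorm(1, params$lambda_d, sd)),
                   abs(rnorm(1, params$lambda_l, sd)))
}

#' Metropolis acceptance ratio for a tree move
#'
#' `min(exp(loglik_new - loglik_old + log_hastings_ratio), 1)`.
#'
#' @param loglik_new,loglik_old Log-likelihoods of proposed/current states.
#' @param log_hastings_ratio Log proposal ratio `q(T|T') / q(T'|T)`.
#' @return Acceptance probability in \[0, 1\].
#' @export
acceptance_ratio_tree <- function(loglik_new, loglik_old, log_hastings_ratio = 0) {
  min(exp(loglik_new - loglik_old + log_hastings_ratio), 1)
}

#' Metropolis acceptance ratio for an error-rate move
#'
#' Includes the prior ratio of the new and current error rates:
#' `min(exp(dloglik + dlogprior + log_hastings_ratio), 1)`. A proposal
#' outside the prior support (log-prior `-Inf`) has acceptance 0.
#'
#' @param loglik_new,loglik_old Log-likelihoods.
#' @param log_prior_new,log_prior_old Log prior densities.
#' @param log_hastings_ratio Log proposal ratio.
#' @return Acceptance probability in \[0, 1\].
#' @export
acceptance_ratio_error <- function(loglik_new, loglik_old,
                                   log_prior_new, log_prior_old,
                                   log_hastings_ratio = 0) {
  if (!is.finite(log_prior_new)) return(0)
  min(exp(loglik_new - loglik_old + log_prior_new - log_prior_old +
            log_hastings_ratio), 1)
}
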