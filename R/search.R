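#' Configuration of the stochastic search
#'
#' At each iteration one categorical draw selects the move type: with
#' probability `p_error_move` the error rates are perturbed, with
#' `p_model_move` the evolution-model rates, and otherwise a tree move is
#' drawn from `move_weights` (branch-length multiplier or one of five
#' topology rearrangements). Proposals that improve the likelihood are
#' always accepted; with probability `eps_mh` a tree or error-rate proposal
#' is instead judged by its Metropolis acceptance ratio, which lets the
#' search escape local optima. Evolution-parameter moves are accepted
#' greedily only.
#'
#' @param max_iterations Iteration budget.
#' @param no_improve_window Stop early when the best log-likelihood has not
#'   improved by more than 1e-6 within this many iterations.
#' @param move_weights Named probabilities (summing to 1) for
#'   `branch`, `rSPR`, `eSPR`, `stNNI`, `rSTS`, `eSTS`.
#' @param p_error_move,p_model_move Per-iteration probabilities of
#'   proposing new error rates / evolution parameters.
#' @param eta Branch-length multiplier tuning parameter.
#' @param eps_mh Probability of Metropolis-style (rather than greedy)
#'   acceptance for tree and error moves.
#' @param proposal_sd_theta,proposal_sd_lambda Normal proposal standard
#'   deviations.
#' @param theta_prior_conc Total concentration of the Beta priors on alpha
#'   and beta (prior means come from the user's input error-rate
#'   estimates; the small concentration encodes a wide prior).
#' @param lambda_prior_shape1,lambda_prior_shape2 Beta prior shapes for the
#'   relative rates lambda_d and lambda_l.
#' @param extension_prob Extension probability of eSPR/eSTS.
#' @param seed Integer seed; fixing it makes the whole run reproducible.
#' @return An object of class `search_config`.
#' @export
search_config <- function(max_iterations = 50000L,
                          no_improve_window = 20000L,
                          move_weights = c(branch = 0.4, rSPR = 0.12,
                                           eSPR = 0.12, stNNI = 0.12,
                                           rSTS = 0.12, eSTS = 0.12),
                          p_error_move = 0.1,
                          p_model_move = 0.1,
                          eta = 0.5,
                          eps_mh = 0.1,
                          proposal_sd_theta = 0.05,
                          proposal_sd_lambda = 0.05,
                          theta_prior_conc = 10,
                          lambda_prior_shape1 = 1.5,
                          lambda_prior_shape2 = 10,
                          extension_prob = 0.8,
                          seed = 1L) {
  nm <- c("branch", "rSPR", "eSPR", "stNNI", "rSTS", "eSTS")
  stopifnot(setequal(names(move_weights), nm),
            abs(sum(move_weights) - 1) < 1e-9,
            all(move_weights >= 0),
            p_error_move >= 0, p_model_move >= 0,
            p_error_move + p_model_move < 1,
            eps_mh >= 0, eps_mh <= 1,
            proposal_sd_theta > 0, proposal_sd_lambda > 0,
            max_iterations >= 1, no_improve_window >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 no_improve_window = as.integer(no_improve_window),
                 move_weights = move_weights[nm],
                 p_error_move = p_error_move, p_model_move = p_model_move,
                 eta = eta, eps_mh = eps_mh,
                 proposal_sd_theta = proposal_sd_theta,
                 proposal_sd_lambda = proposal_sd_lambda,
                 theta_prior_conc = theta_prior_conc,
                 lambda_prior_shape1 = lambda_prior_shape1,
                 lambda_prior_shape2 = lambda_prior_shape2,
                 extension_prob = extension_prob,
                 seed = as.integer(seed)),
            class = "search_config")
}

.beta_prior_logdens <- function(x, mean, conc) {
  mean <- min(max(mean, 1e-4), 1 - 1e-4)
  dbeta(x, mean * conc, (1 - mean) * conc, log = TRUE)
}

.theta_log_prior <- function(theta, theta0, conc) {
  .beta_prior_logdens(theta$alpha, theta0$alpha, conc) +
    .beta_prior_logdens(theta$beta, theta0$beta, conc)
}

#' Joint stochastic search for tree, error rates and model parameters
#'
#' Maximum-likelihood inference by hill climbing with occasional
#' Metropolis-style acceptance over the joint space of rooted binary tree
#' topologies, branch lengths, error rates (alpha, beta) and finite-sites
#' model parameters (lambda_d, lambda_l). Returns the best configuration
#' ever visited. Fully reproducible given `config$seed`.
#'
#' @param D A [genotype_matrix()] with at least 4 cells.
#' @param config A [search_config()].
#' @param theta0 Initial [error_rates()] estimate (also sets the prior
#'   means for the error-rate Metropolis branch).
#' @param params0 Initial [evolution_params()].
#' @param start_tree Optional starting `phylo`; by default a random
#'   topology with all branch lengths `1/n`.
#' @param verbose Print a likelihood checkpoint every 10,000 iterations.
#' @return List with `best` (list: `tree`, `theta`, `params`, `loglik`) and
#'   `trace` (data frame: iteration, move, accepted, loglik, best_loglik),
#'   plus `iterations_run` and the resolved `config`.
#' @export
run_search <- function(D, config = search_config(), theta0, params0,
                       start_tree = NULL, verbose = FALSE) {
  stopifnot(inherits(D, "genotype_matrix"), inherits(config, "search_config"),
            inherits(theta0, "error_rates"), inherits(params0, "evolution_params"))
  m <- ncol(D$values); n <- nrow(D$values)
  if (m < 4L) stop("need at least 4 cells for topology moves")
  set.seed(config$seed)
  k <- length(mode_states(D$mode))

  if (is.null(start_tree)) {
    tree <- random_binary_tree(m, labels = D$cell_ids)
    tree$edge.length <- rep(1 / n, nrow(tree$edge))
  } else {
    validate_phylo(start_tree)
    if (!setequal(start_tree$tip.label, D$cell_ids))
      stop("start_tree leaves do not match matrix cells")
    tree <- start_tree
  }
  vals <- D$values[, tree$tip.label, drop = FALSE]
  eval_ll <- function(tr, th, pa)
    sum(.loglik_engine(tr, vals, th$alpha, th$beta, pa$lambda_d, pa$lambda_l, k))

  theta <- theta0; params <- params0
  ll <- eval_ll(tree, theta, params)
  best <- list(tree = tree, theta = theta, params = params, loglik = ll)
  last_improve <- 0L

  move_names <- c("error", "model", names(config$move_weights))
  move_probs <- c(config$p_error_move, config$p_model_move,
                  (1 - config$p_error_move - config$p_model_move) * config$move_weights)

  it_max <- config$max_iterations
  tr_move <- character(it_max); tr_acc <- logical(it_max)
  tr_ll <- numeric(it_max); tr_best <- numeric(it_max)

  for (it in seq_len(it_max)) {
    mv <- sample(move_names, 1L, prob = move_probs)
    new_tree <- tree; new_theta <- theta; new_params <- params
    log_hr <- 0; dlogprior <- 0; mh_allowed <- TRUE
    if (mv == "error") {
      new_theta <- propose_error_rates(theta, config$proposal_sd_theta)
      dlogprior <- .theta_log_prior(new_theta, theta0, config$theta_prior_conc) -
        .theta_log_prior(theta, theta0, config$theta_prior_conc)
    } else if (mv == "model") {
      new_params <- propose_evolution_params(params, config$proposal_sd_lambda)
      mh_allowed <- FALSE  # greedy only
    } else if (mv == "branch") {
      pr <- propose_branch_lengths(tree, config$eta)
      new_tree <- pr$tree; log_hr <- pr$log_hastings_ratio
    } else {
      pr <- propose_topology(tree, mv, config$extension_prob)
      new_tree <- pr$tree; log_hr <- pr$log_hastings_ratio
    }
    new_ll <- eval_ll(new_tree, new_theta, new_params)
    accept <- new_ll > ll
    if (!accept && mh_allowed && config$eps_mh > 0 && runif(1) < config$eps_mh) {
      rho <- if (mv == "error")
        acceptance_ratio_error(new_ll, ll, dlogprior, 0, log_hr)
      else
        acceptance_ratio_tree(new_ll, ll, log_hr)
      accept <- runif(1) < rho
    }
    if (accept) {
      tree <- new_tree; theta <- new_theta; params <- new_params; ll <- new_ll
      if (ll > best$loglik + 1e-6) {
        best <- list(tree = tree, theta = theta, params = params, loglik = ll)
        last_improve <- it
      }
    }
    tr_move[it] <- mv; tr_acc[it] <- accept
    tr_ll[it] <- ll; tr_best[it] <- best$loglik
    if (verbose && it %% 10000L == 0L)
      message(sprintf("iteration %d: loglik %.4f (best %.4f)", it, ll, best$loglik))
    if (it - last_improve >= config$no_improve_window) break
  }

  ran <- it
  # canonicalize the best tree (clean ape ordering for downstream use)
  best$tree <- parse_newick(write_newick(best$tree, precision = 15L))
  list(best = best,
       trace = data.frame(iteration = seq_len(ran), move = tr_move[seq_len(ran)],
                          accepted = tr_acc[seq_len(ran)], loglik = tr_ll[seq_len(ran)],
                          best_loglik = tr_best[seq_len(ran)],
                          stringsAsFactors = FALSE),
       iterations_run = ran, config = config)
}
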