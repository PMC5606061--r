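test_that("branch-length proposal scales branches within the multiplier bounds", {
  set.seed(201)
  tr <- random_test_tree(8)
  pr <- propose_branch_lengths(tr, eta = 0)
  expect_equal(pr$tree$edge.length, tr$edge.length)
  expect_equal(pr$log_hastings_ratio, 0)
  for (eta in c(0.5, 2)) {
    pr <- propose_branch_lengths(tr, eta)
    r <- pr$tree$edge.length / tr$edge.length
    expect_true(all(r >= exp(-eta / 2) & r < exp(eta / 2)))
    expect_equal(pr$log_hastings_ratio, sum(log(r)), tolerance = 1e-12)
    expect_equal(pr$tree$edge, tr$edge)  # topology untouched
  }
})

test_that("every topology move returns a valid rooted binary tree on the same leaves", {
  set.seed(203)
  moves <- c("rSPR", "eSPR", "stNNI", "rSTS", "eSTS")
  for (rep in 1:15) {
    tr <- random_test_tree(sample(4:12, 1))
    for (mv in moves) {
      out <- propose_topology(tr, mv)
      expect_silent(validate_phylo(out$tree))
      expect_setequal(out$tree$tip.label, tr$tip.label)
      expect_equal(out$log_hastings_ratio, 0)
    }
  }
  expect_error(propose_topology(parse_newick("((A:1,B:1):1,C:1);"), "rSPR"),
               "at least 4")
})

test_that("stNNI explores the 4-leaf quartet neighbourhood", {
  set.seed(205)
  tr <- parse_newick("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  quartets <- character(0)
  for (i in 1:200) {
    out <- propose_topology(tr, "stNNI")
    quartets <- c(quartets, bipartition_encoding(out$tree))
  }
  # one move always yields one of the other two unrooted quartet topologies
  expect_setequal(unique(quartets), c("A|C", "A|D"))
})

test_that("repeated rSPR reaches every rooted topology on 5 leaves", {
  set.seed(207)
  tr <- random_test_tree(5)
  seen <- character(0)
  for (i in 1:10000) {
    tr <- propose_topology(tr, "rSPR")$tree
    seen <- c(seen, topology_key(tr))
    if (length(unique(seen)) == 105) break
  }
  expect_equal(length(unique(seen)), topology_count(5))
})

test_that("parameter proposals stay in support and are symmetric by reflection", {
  set.seed(209)
  th <- error_rates(0.02, 0.95)
  out <- replicate(500, {
    p <- propose_error_rates(th, sd = 0.3)
    c(p$alpha, p$beta)
  })
  expect_true(all(out > 0 & out < 1))
  # reflection density is symmetric: q(y|x) == q(x|y) on a grid
  refl_dens <- function(y, x, sd) {
    ks <- -10:10
    sum(dnorm(2 * ks + y, x, sd) + dnorm(2 * ks - y, x, sd))
  }
  for (x in c(0.05, 0.4, 0.9)) for (y in c(0.1, 0.5, 0.97))
    expect_equal(refl_dens(y, x, 0.2), refl_dens(x, y, 0.2), tolerance = 1e-10)
  pl <- replicate(200, unlist(propose_evolution_params(evolution_params(0.01, 2), 0.5)))
  expect_true(all(pl >= 0))
})

test_that("acceptance ratios reproduce the Metropolis formulas", {
  expect_equal(acceptance_ratio_tree(-10, -10, 0), 1)
  expect_equal(acceptance_ratio_tree(-10 - log(2), -10, 0), 0.5)
  expect_equal(acceptance_ratio_tree(-5, -10, 0), 1)  # capped at 1
  expect_equal(acceptance_ratio_error(-10, -10, 0, 0, 0), 1)
  expect_equal(acceptance_ratio_error(-10, -10, log(2), 0, 0), 1)  # min(2,1)
  expect_equal(acceptance_ratio_error(-10, -10, -Inf, 0, 0), 0)   # out of support
})

test_that("the search is deterministic, monotone in best-so-far, and greedy at eps 0", {
  cfg <- simulation_config(m = 6, n = 60, seed = 42)
  sim <- simulate_dataset(cfg)
  th <- error_rates(0.01, 0.2); pa <- evolution_params(0.1, 0.1)
  sc <- search_config(max_iterations = 1500, seed = 99)
  r1 <- run_search(sim$D, sc, th, pa)
  r2 <- run_search(sim$D, sc, th, pa)
  expect_identical(r1$trace, r2$trace)
  expect_identical(write_newick(r1$best$tree), write_newick(r2$best$tree))
  expect_true(all(diff(r1$trace$best_loglik) >= 0))
  # recorded best equals recomputing the likelihood of the best state
  expect_equal(r1$best$loglik,
               total_log_likelihood(r1$best$tree, sim$D, r1$best$theta, r1$best$params),
               tolerance = 1e-8)

  # pure hill-climbing never accepts a worse configuration
  sc0 <- search_config(max_iterations = 1500, eps_mh = 0, seed = 7)
  r0 <- run_search(sim$D, sc0, th, pa)
  chg <- diff(r0$trace$loglik)
  expect_true(all(chg[chg != 0] > 0))

  small <- genotype_matrix(matrix(0:1, 4, 3), "binary")
  expect_error(run_search(small, sc, th, pa), "at least 4")
})
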