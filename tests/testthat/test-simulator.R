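test_that("random trees are valid and cover the topology space", {
  set.seed(401)
  two <- random_binary_tree(2)
  expect_length(two$tip.label, 2L)
  for (rep in 1:20) {
    m <- sample(4:50, 1)
    tr <- random_binary_tree(m)
    expect_silent(validate_phylo(tr))
    expect_length(tr$tip.label, m)
    # realized mean root-to-leaf height is the configured target
    d <- ape::node.depth.edgelength(tr)
    expect_equal(mean(d[seq_len(m)]), 0.5, tolerance = 1e-9)
  }
  # all 15 labelled rooted shapes on 4 leaves appear
  keys <- replicate(5000, topology_key(random_binary_tree(4)))
  expect_equal(length(unique(keys)), 15L)
})

test_that("genotype evolution honours the finite-sites event model", {
  set.seed(403)
  # no events at zero branch lengths
  tr <- random_binary_tree(6)
  tr$edge.length <- rep(0, nrow(tr$edge))
  cfg <- simulation_config(m = 6, n = 50, loh_prob = 0, del_prob = 0)
  ev <- evolve_genotypes(tr, cfg)
  expect_true(all(ev$G$values == 0L))

  # infinite-sites regime: each site mutates at most once; binarized truth
  # passes the four-gamete test
  # low height avoids exhausting the fresh-site pool (which would force
  # recurrent events by the corner-case rule)
  for (s in 1:20) {
    cfg0 <- simulation_config(m = 8, n = 100, recur_prob = 0, loh_prob = 0,
                              del_prob = 0, alpha = 0, beta_mean = 0,
                              tree_height = 0.05, seed = s)
    sim <- simulate_dataset(cfg0)
    expect_equal(four_gamete_test(binarize(sim$G))$violating_pairs, 0L)
    expect_true(all(sim$G$values %in% 0:1))
  }

  # per-branch new-mutation count has mean ~ t * n
  n <- 400; t <- 0.2
  tr2 <- parse_newick(sprintf("(A:%g,B:0);", t))
  cfg2 <- simulation_config(m = 4, n = n, recur_prob = 0, loh_prob = 0, del_prob = 0)
  counts <- replicate(1000, {
    ev <- evolve_genotypes(tr2, cfg2)
    sum(ev$G$values[, "A"] != 0)
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - t * n), 3 * se + 1e-9)
})

test_that("doublet merging follows the expected-genotype operator", {
  pairs <- expand.grid(g1 = 0:2, g2 = 0:2)
  merged <- doublet_merge(pairs$g1, pairs$g2)
  expected <- c(0, 1, 1,
                1, 1, 1,
                1, 1, 2)  # rows g1 = 0,1,2 x cols g2 = 0,1,2 (column-major)
  expect_equal(merged, expected)
  expect_equal(doublet_merge(pairs$g2, pairs$g1), merged)  # commutative
  expect_equal(doublet_merge(0:2, 0:2), 0:2)               # idempotent

  set.seed(405)
  cfg <- simulation_config(m = 8, n = 30, seed = 5)
  sim <- simulate_dataset(cfg)
  same <- inject_doublets(sim$G, 0)
  expect_equal(same$values, sim$G$values)
  expect_length(attr(same, "doublet_cells"), 0L)
  dbl <- inject_doublets(sim$G, 1)
  expect_true(all(dbl$values %in% 0:2))
  expect_length(attr(dbl, "doublet_cells"), 8L)
})

test_that("error injection matches the observation model statistics", {
  set.seed(407)
  cfg <- simulation_config(m = 12, n = 100, seed = 9)
  sim <- simulate_dataset(cfg)
  clean <- add_errors(sim$G, 0, 0)
  expect_equal(clean$values, sim$G$values)

  # large matrix: empirical FP fraction ~ alpha, and true 2s never change
  n <- 5000; m <- 30
  vals <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(0.6, 0.3, 0.1)), n, m)
  G <- genotype_matrix(vals, "ternary")
  alpha <- 0.01
  D <- add_errors(G, alpha, beta_mean = 0.2)
  zeros <- which(G$values == 0L)
  flips <- mean(D$values[zeros] == 1L)
  se <- sqrt(alpha * (1 - alpha) / length(zeros))
  expect_lt(abs(flips - alpha), 3 * se)
  expect_true(all(D$values[G$values == 2L] == 2L))
  # per-cell dropout rates concentrate on the configured distribution
  b <- attr(D, "beta_c")
  expect_lt(abs(mean(b) - 0.2), 3 * 0.02 / sqrt(m))
})

test_that("missing-data masking is Bernoulli per entry", {
  set.seed(409)
  cfg <- simulation_config(m = 10, n = 500, seed = 3)
  sim <- simulate_dataset(cfg)
  expect_equal(mask_missing(sim$D, 0)$values, sim$D$values)
  expect_true(all(is.na(mask_missing(sim$D, 1)$values)))
  p <- 0.25
  f <- mean(is.na(mask_missing(sim$D, p)$values))
  se <- sqrt(p * (1 - p) / length(sim$D$values))
  expect_lt(abs(f - p), 3 * se)
})

test_that("the full pipeline is reproducible from its seed", {
  cfg <- simulation_config(m = 9, n = 50, doublet_rate = 0.2, missing_prob = 0.1,
                           seed = 2024)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  expect_identical(a$G$values, b$G$values)
  expect_identical(a$D$values, b$D$values)
  expect_identical(a$beta_c, b$beta_c)
  expect_identical(a$doublet_cells, b$doublet_cells)
})
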