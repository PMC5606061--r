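test_that("Newick parsing reads structure and rejects malformed input", {
  tr <- parse_newick("((A:0.1,B:0.2):0.3,C:0.4);")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(tr$Nnode, 2L)
  root_children <- tr$edge[tr$edge[, 1] == 4, 2]
  expect_length(root_children, 2L)

  expect_error(parse_newick("((A,B),(C,D),(E,F));"), "non-binary")
  expect_error(parse_newick("((A,B);"), "unbalanced")
  expect_error(parse_newick("(A,B)"), ";")
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")
})

test_that("Newick writing is canonical, deterministic, and round-trips", {
  set.seed(11)
  for (m in c(4, 7, 10)) {
    tr <- random_test_tree(m)
    s1 <- write_newick(tr)
    tr2 <- parse_newick(s1)
    expect_identical(write_newick(tr2), s1)  # fixed point
    expect_setequal(tr2$tip.label, tr$tip.label)
    # lengths survive to printed precision
    expect_equal(sort(tr2$edge.length), sort(signif(tr$edge.length, 6)),
                 tolerance = 1e-6)
  }
  # child order is by smallest descendant label regardless of input rotation
  a <- parse_newick("((B:0.2,A:0.1):0.3,C:0.4);")
  b <- parse_newick("(C:0.4,(A:0.1,B:0.2):0.3);")
  expect_identical(write_newick(a), write_newick(b))
  # zero lengths are printed, not omitted
  expect_identical(write_newick(parse_newick("(A:0.1,B:0);")), "(A:0.1,B:0.0);")
})

test_that("bipartition encoding matches the edge-deletion oracle", {
  quartet <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_identical(bipartition_encoding(quartet), "A|B")
  expect_identical(bipartition_encoding(parse_newick("((A:1,B:1):1,C:1);")),
                   character(0))
  set.seed(21)
  for (m in 4:10) {
    tr <- random_test_tree(m)
    enc <- bipartition_encoding(tr)
    expect_length(enc, m - 3L)  # binary tree: m - 3 non-trivial splits
    expect_identical(enc, oracle_splits(tr))
  }
})

test_that("FN/FP/RF distances follow the bipartition definitions", {
  t1 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(tree_distances(t1, t1), list(fn = 0, fp = 0, rf = 0))
  expect_equal(tree_distances(t1, t2), list(fn = 1, fp = 1, rf = 1))
  expect_error(tree_distances(t1, parse_newick("((A:1,B:1):1,(C:1,E:1):1);")),
               "leaf sets differ")

  set.seed(31)
  for (rep in 1:10) {
    m <- sample(4:10, 1)
    ta <- random_test_tree(m)
    tb <- random_test_tree(m)
    da <- tree_distances(ta, tb)
    db <- tree_distances(tb, ta)
    # binary trees: fn == fp == rf, and symmetric
    expect_equal(da$fn, da$fp)
    expect_equal(da$rf, db$rf)
    expect_gte(da$rf, 0); expect_lte(da$rf, 1)
    # brute-force symmetric difference over enumerated splits
    sa <- oracle_splits(ta); sb <- oracle_splits(tb)
    expect_equal(da$rf, (length(setdiff(sa, sb)) / length(sa) +
                           length(setdiff(sb, sa)) / length(sb)) / 2)
    # independent cross-check against phangorn's RF count
    rf_count <- phangorn::RF.dist(ape::unroot(ta), ape::unroot(tb))
    expect_equal(da$rf, rf_count / (2 * (m - 3)))
  }
})

test_that("path distances equal the graph-search oracle", {
  two <- parse_newick("(A:0.1,B:0.2);")
  expect_equal(path_distance_matrix(two)["A", "B"], 0.3)
  set.seed(41)
  for (rep in 1:5) {
    tr <- random_test_tree(8)
    d <- path_distance_matrix(tr)
    expect_equal(diag(d), setNames(rep(0, 8), tr$tip.label))
    expect_equal(d, t(d))
    expect_equal(d, oracle_path_distances(tr)[rownames(d), colnames(d)])
  }
})

test_that("lineage trees project labelled internal cells to pendant leaves", {
  chain <- lineage_to_phylogeny(data.frame(parent = c("A", "B"), child = c("B", "C")))
  expect_setequal(chain$tip.label, c("A", "B", "C"))
  # C is two edges below the root, with A and B pendant along the path
  d <- path_distance_matrix(chain)
  expect_equal(d["A", "B"], 1)
  expect_equal(d["A", "C"], 2)
  expect_equal(d["B", "C"], 1)

  # labels only on leaves: topology unchanged
  star <- lineage_to_phylogeny(data.frame(parent = c("R", "R", "R"),
                                          child = c("X", "Y", "Z")))
  expect_setequal(star$tip.label, c("R", "X", "Y", "Z"))
  expect_error(lineage_to_phylogeny(data.frame(parent = c("A", "A"),
                                               child = c("B", "B"))),
               "duplicate")
  # leaf count = number of labelled nodes (here r, a, b, c, d)
  ed <- data.frame(parent = c("r", "r", "a", "a"), child = c("a", "b", "c", "d"))
  expect_length(lineage_to_phylogeny(ed)$tip.label, 5L)
})

test_that("topology counts follow the double-factorial growth", {
  expect_equal(topology_count(2), 1)
  expect_equal(topology_count(3), 3)
  expect_equal(topology_count(4), 15)
  expect_equal(topology_count(5), 105)
  expect_error(topology_count(1), "at least 2")
  # arbitrary precision beyond double range: check a known recurrence digit-exactly
  big <- topology_count(40)
  expect_type(big, "character")
  # (2m-3)!! for m=40 ends in the digits of the product mod 10^6
  odds <- seq(1, 77, by = 2)
  tail_mod <- 1
  for (f in odds) tail_mod <- (tail_mod * f) %% 1e6
  expect_identical(substring(big, nchar(big) - 5), sprintf("%06d", tail_mod))
})
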