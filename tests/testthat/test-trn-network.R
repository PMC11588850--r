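test_that("TF graph keeps only regulator nodes, drops self-loops and duplicates", {
  reg <- reg_df(c("a", "b", "a"), c("b", "c", "g1"),
                c("activation", "repression", "activation"))
  g <- build_tf_graph(rbind(reg, reg_df("c", "g2")))
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  edges <- igraph::as_data_frame(g)
  expect_equal(nrow(edges), 2)
  expect_setequal(paste(edges$from, edges$to), c("a b", "b c"))

  g2 <- build_tf_graph(reg_df("a", "a"))
  expect_equal(igraph::V(g2)$name, "a")
  expect_equal(igraph::ecount(g2), 0)

  dup <- rbind(reg_df("a", "b"), reg_df("a", "b", "repression"),
               reg_df("b", "g1"))
  expect_equal(igraph::ecount(build_tf_graph(dup)), 1)

  expect_error(build_tf_graph(reg_df(character(), character())), "empty")
})

test_that("component fraction matches weak-component sizes", {
  expect_equal(component_fraction(build_tf_graph(reg_df("a", "a"))), 1)
  two_comp <- rbind(reg_df(c("a", "b"), c("b", "a")),
                    reg_df(c("c", "d"), c("d", "c")))
  expect_equal(component_fraction(build_tf_graph(two_comp)), 0.5)
})

test_that("pair connectivity counts ordered reachable pairs", {
  chain <- rbind(reg_df(c("a", "b"), c("b", "c")), reg_df("c", "g1"))
  g <- build_tf_graph(chain)
  expect_equal(pair_connectivity(g), 0.5)   # (a,b),(b,c),(a,c) of 6

  complete <- reg_df(rep(c("a", "b", "c"), each = 2),
                     c("b", "c", "a", "c", "a", "b"))
  expect_equal(pair_connectivity(build_tf_graph(complete)), 1)

  edgeless <- reg_df(c("a", "b"), c("g1", "g2"))
  expect_equal(pair_connectivity(build_tf_graph(edgeless)), 0)
  expect_error(pair_connectivity(build_tf_graph(reg_df("a", "a"))), "2 nodes")
})

test_that("removal impact reports both the new fraction and the relative drop", {
  chain <- rbind(reg_df(c("a", "b"), c("b", "c")), reg_df("c", "g1"))
  g <- build_tf_graph(chain)
  out <- removal_impact(g, "b")
  expect_equal(out$new_fraction, 0)
  expect_equal(out$relative_drop_percent, 100)

  # removing an isolated node raises connectivity: relative drop <= 0
  with_iso <- rbind(chain, reg_df("d", "g2"))
  g4 <- build_tf_graph(with_iso)
  out4 <- removal_impact(g4, "d")
  f0 <- pair_connectivity(g4)
  expect_equal(out4$new_fraction, 0.5)
  expect_lte(out4$relative_drop_percent, 0)
  expect_equal(out4$relative_drop_percent, 100 * (f0 - 0.5) / f0)

  expect_error(removal_impact(g, "zz"), "not in the graph")
  edgeless <- reg_df(c("a", "b", "c"), c("g1", "g2", "g3"))
  expect_warning(res <- removal_impact(build_tf_graph(edgeless), "a"),
                 "undefined")
  expect_true(is.na(res$relative_drop_percent))
})

test_that("betweenness is normalized directed shortest-path centrality", {
  chain <- rbind(reg_df(c("a", "b"), c("b", "c")), reg_df("c", "g1"))
  b <- tf_betweenness(build_tf_graph(chain))
  expect_equal(unname(b["b"]), 0.5)
  expect_equal(unname(b[c("a", "c")]), c(0, 0))

  complete <- reg_df(rep(c("a", "b", "c"), each = 2),
                     c("b", "c", "a", "c", "a", "b"))
  expect_equal(max(tf_betweenness(build_tf_graph(complete))), 0)

  # star with two-way edges: center is maximal
  leaves <- paste0("l", 1:4)
  star <- rbind(reg_df(rep("c", 4), leaves), reg_df(leaves, rep("c", 4)))
  b <- tf_betweenness(build_tf_graph(star))
  expect_true(all(b["c"] > b[leaves]))
})

test_that("path-through fraction handles pair and path modes", {
  chain <- rbind(reg_df(c("a", "b"), c("b", "c")), reg_df("c", "g1"))
  g <- build_tf_graph(chain)
  expect_equal(path_through_fraction(g, "b", "pair"), 1)
  expect_equal(path_through_fraction(g, "b", "path"), 1)

  edgeless <- reg_df(c("a", "b", "c"), c("g1", "g2", "g3"))
  expect_error(path_through_fraction(build_tf_graph(edgeless), "a"),
               "no connected")
  expect_error(path_through_fraction(g, "zz"), "not in the graph")
})

test_that("path mode times eligible pairs equals the betweenness numerator", {
  set.seed(51)
  for (rep in 1:20) {
    adj <- random_adjacency(8, 0.35)
    g <- graph_from_adjacency(adj)
    n <- nrow(adj)
    bw_num <- igraph::betweenness(g, directed = TRUE)
    for (x in sample(n, 2)) {
      D <- oracle_distances(adj)
      den <- sum(vapply(seq_len(n), function(s) sum(
        is.finite(D[s, ]) & seq_len(n) != s & seq_len(n) != x & s != x),
        numeric(1)))
      if (den == 0) next
      frac <- path_through_fraction(g, rownames(adj)[x], "path")
      expect_equal(frac * den, unname(bw_num[x]), tolerance = 1e-12)
    }
  }
})

test_that("regulon subnetwork skewness follows the Fisher-Pearson formula", {
  star <- reg_df(rep("tf", 5), paste0("l", 1:5))
  expect_equal(regulon_subnetwork_skewness(star, "tf"), 4 / sqrt(5))

  sym <- rbind(reg_df(rep("tf", 3), c("a", "b", "c")), reg_df("a", "b"))
  expect_equal(regulon_subnetwork_skewness(sym, "tf"), 0)

  flat <- rbind(reg_df(rep("tf", 3), c("a", "b", "c")),
                reg_df(c("a", "b", "c"), c("b", "c", "a")))
  expect_warning(val <- regulon_subnetwork_skewness(flat, "tf"),
                 "zero variance")
  expect_true(is.na(val))

  expect_error(regulon_subnetwork_skewness(reg_df("tf", "a"), "tf"),
               "at least 3")
})

test_that("sole-regulator counts and regulators-per-gene follow definitions", {
  reg <- reg_df(c("a", "a", "b"), c("g1", "g2", "g2"))
  counts <- sole_regulator_counts(reg)
  expect_equal(counts, c(a = 1L, b = 0L))

  dual <- reg_df(c("a", "b", "a", "b"), c("g1", "g1", "g2", "g2"))
  expect_true(all(sole_regulator_counts(dual) == 0))

  expect_equal(unname(regulators_per_gene(reg, c("g2", "g1", "nope"))),
               c(2L, 1L, 0L))
  expect_error(regulators_per_gene(reg, character()), "empty")

  # random fixture vs brute-force recount
  set.seed(9)
  rnd <- reg_df(sample(paste0("t", 1:5), 40, replace = TRUE),
                sample(paste0("g", 1:20), 40, replace = TRUE))
  rnd <- rnd[rnd$regulator != rnd$target, ]
  counts <- sole_regulator_counts(rnd)
  for (tf in names(counts)) {
    brute <- 0
    for (g in unique(rnd$target[rnd$regulator == tf]))
      if (length(unique(rnd$regulator[rnd$target == g])) == 1) brute <- brute + 1
    expect_equal(unname(counts[tf]), brute)
  }
})

test_that("connectivity properties hold on random graphs", {
  set.seed(77)
  for (rep in 1:30) {
    adj <- random_adjacency(sample(3:9, 1), 0.3)
    g <- graph_from_adjacency(adj)
    cf <- component_fraction(g)
    expect_equal(cf == 1, igraph::is_connected(g, mode = "weak"))
    # deleting an edge never increases pair connectivity
    if (igraph::ecount(g) > 0) {
      f0 <- pair_connectivity(g)
      g2 <- igraph::delete_edges(g, sample(igraph::ecount(g), 1))
      expect_lte(pair_connectivity(g2), f0 + 1e-15)
    }
  }
})
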