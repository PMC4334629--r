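two_triangles <- function() {
  igraph::make_graph(~ a - b - c - a, d - e - f - d, c - d)
}

test_that("community detection recovers obvious structure", {
  g <- two_triangles()
  part <- detect_communities(g, "edge_betweenness")
  expect_equal(length(unique(part)), 2L)
  expect_equal(part[["a"]], part[["b"]])
  expect_equal(part[["a"]], part[["c"]])
  expect_false(part[["a"]] == part[["d"]])
  # complete graph: a single community under all three algorithms
  k <- igraph::make_full_graph(6)
  igraph::V(k)$name <- letters[1:6]
  for (alg in c("edge_betweenness", "walktrap", "label_propagation"))
    expect_equal(length(unique(detect_communities(k, alg, seed = 2))), 1L)
  # disconnected graphs: communities respect components
  g2 <- igraph::make_graph(~ a - b, c - d)
  part2 <- detect_communities(g2, "walktrap")
  expect_false(part2[["a"]] == part2[["c"]])
})

test_that("Newman-Girvan modularity matches closed forms and oracles", {
  g <- two_triangles()
  all_one <- stats::setNames(rep(1, 6), igraph::V(g)$name)
  expect_equal(newman_girvan_modularity(g, all_one), 0)
  # two disjoint triangles split by component: Q = 0.5
  tt <- igraph::make_graph(~ a - b - c - a, d - e - f - d)
  bycomp <- stats::setNames(rep(1:2, each = 3), igraph::V(tt)$name)
  expect_equal(newman_girvan_modularity(tt, bycomp), 0.5)
  # agreement with edge-accumulation oracle and igraph on random cases
  for (seed in 1:5) {
    gr <- random_graph(8, 0.45, seed = seed)
    part <- stats::setNames(sample(1:3, 8, replace = TRUE),
                            igraph::V(gr)$name)
    q <- newman_girvan_modularity(gr, part)
    expect_equal(q, bf_modularity(gr, part), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(gr, part[igraph::V(gr)$name]),
                 tolerance = 1e-12)
  }
  # edgeless graph: undefined
  e <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(e)$name <- letters[1:3]
  expect_true(is.na(newman_girvan_modularity(
    e, stats::setNames(1:3, letters[1:3]))))
})

test_that("no partition beats the exhaustive maximum on small graphs", {
  set.seed(31)
  for (seed in 1:2) {
    g <- random_graph(7, 0.4, seed = seed + 10)
    nodes <- igraph::V(g)$name
    # exhaustive search over all partitions via restricted growth strings
    best <- -Inf
    grow <- function(assign, next_max) {
      if (length(assign) == length(nodes)) {
        q <- newman_girvan_modularity(g, stats::setNames(assign, nodes))
        best <<- max(best, q, na.rm = TRUE)
        return(invisible())
      }
      for (k in seq_len(next_max + 1))
        grow(c(assign, k), max(next_max, k))
    }
    grow(integer(0), 0L)
    for (i in 1:20) {
      part <- stats::setNames(sample(1:4, length(nodes), TRUE), nodes)
      expect_lte(newman_girvan_modularity(g, part), best + 1e-12)
    }
    # detected communities never exceed the true optimum either
    part <- detect_communities(g, "edge_betweenness")
    expect_lte(newman_girvan_modularity(g, part), best + 1e-12)
  }
})

test_that("predictor evaluation counts matches greedily and symmetrically", {
  cat <- complex_catalog(c("root", "s1", "s2"),
                         list(c("a", "b", "c", "d", "e", "f"),
                              c("a", "b", "c"), c("d", "e", "f")),
                         bait = c("a", "a", "d"))
  groups <- nested_groups(find_nested_pairs(all_pairs(cat), cat), cat)
  gr <- groups[[1]]
  # communities exactly equal to the subcomplexes
  part <- stats::setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "d", "e", "f"))
  ev <- evaluate_as_predictor(part, gr, cat)
  expect_equal(ev[c("tp", "fp", "fn")], list(tp = 2L, fp = 0L, fn = 0L))
  expect_equal(ev$precision, 1)
  expect_equal(ev$fdr, 0)
  expect_equal(ev$precision + ev$fdr, 1)
  # one correct community plus one spurious
  part2 <- stats::setNames(c(1, 1, 1, 2, 3, 3), c("a", "b", "c", "d", "e", "f"))
  ev2 <- evaluate_as_predictor(part2, gr, cat, match_threshold = 0.7)
  expect_equal(ev2$precision, 1 / 3)  # s1 matched; {d} and {e,f} unmatched
  # invariance to community relabeling
  part3 <- stats::setNames(c(9, 9, 9, 4, 4, 4), c("a", "b", "c", "d", "e", "f"))
  ev3 <- evaluate_as_predictor(part3, gr, cat)
  expect_equal(ev3[c("tp", "fp", "fn")], ev[c("tp", "fp", "fn")])
  # tp never exceeds the number of subcomplexes
  part4 <- stats::setNames(1:6, c("a", "b", "c", "d", "e", "f"))
  ev4 <- evaluate_as_predictor(part4, gr, cat, match_threshold = 0.1)
  expect_lte(ev4$tp, 2L)
})

test_that("dense matrix-planted modules are recovered with high precision", {
  # positive control: subcomplexes as dense matrix modules, sparse joins
  cat <- complex_catalog(c("root", "s1", "s2"),
                         list(letters[1:8], letters[1:4], letters[5:8]))
  # matrix expansion of the subcomplexes + a single bridging root edge
  ed <- rbind(expand_matrix(letters[1:4], "s1"),
              expand_matrix(letters[5:8], "s2"),
              data.frame(from = "a", to = "e", complex_id = "root"))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  groups <- nested_groups(find_nested_pairs(all_pairs(cat), cat), cat)
  part <- detect_communities(g, "edge_betweenness")
  ev <- evaluate_as_predictor(part, groups[[1]], cat)
  expect_equal(ev$precision, 1)
  expect_equal(ev$fdr, 0)
  expect_gt(newman_girvan_modularity(g, part), 0.3)
})

test_that("modularity_eval summarizes per group", {
  sim <- generate_catalog(synthetic_spec(seed = 2, n_maximal = 40,
                                         n_proteins = 100))
  dd <- dedupe_catalog(sim$catalog)$catalog
  groups <- nested_groups(find_nested_pairs(all_pairs(dd), dd), dd)
  g <- build_view(dd, "spoke", "multiedge")
  res <- modularity_eval(groups, dd, g, seed = 1)
  expect_equal(nrow(res), length(groups))
  expect_true(all(res$precision + res$fdr == 1 |
                    is.na(res$precision)))
  expect_true(all(res$modularity <= 1 & res$modularity >= -0.5,
                  na.rm = TRUE))
})
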