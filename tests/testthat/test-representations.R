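test_that("spoke expansion yields a star on the hub", {
  mips <- mips_catalog()
  # two-member complex: a single edge between the two subunits
  e <- expand_spoke(mips$members$TIM9_TIM10, "TIM9_TIM10", bait = "TIM9")
  expect_equal(nrow(e), 1L)
  expect_setequal(unlist(e[, c("from", "to")]), c("TIM9", "TIM10"))
  # five-member carrier translocase: 4 edges, all incident to the hub
  e <- expand_spoke(mips$members$TIM22_complex, "TIM22_complex",
                    bait = "TIM22")
  expect_equal(nrow(e), 4L)
  expect_true(all(e$from == "TIM22"))
  expect_setequal(e$to, setdiff(mips$members$TIM22_complex, "TIM22"))
  expect_true(all(e$complex_id == "TIM22_complex"))
  # singleton: no pairs, no edges
  expect_equal(nrow(expand_spoke("P1", "c1")), 0L)
  # missing bait falls back to lexicographic smallest member
  e <- expand_spoke(c("B", "A", "C"), "c2")
  expect_true(all(e$from == "A"))
  # seeded_random is reproducible and requires a seed
  e1 <- expand_spoke(letters[1:5], "c3", hub_policy = "seeded_random", seed = 7)
  e2 <- expand_spoke(letters[1:5], "c3", hub_policy = "seeded_random", seed = 7)
  expect_identical(e1, e2)
  expect_error(expand_spoke(letters[1:5], "c3", hub_policy = "seeded_random"),
               "seed")
})

test_that("matrix expansion yields the complete graph", {
  expect_equal(nrow(expand_matrix(c("P1", "P2", "P3"), "c")), 3L)
  mips <- mips_catalog()
  expect_equal(nrow(expand_matrix(mips$members$TIM22_complex, "c")), 10L)
  # n = 2 degeneracy: spoke and matrix coincide
  sp <- expand_spoke(c("P1", "P2"), "c")
  mx <- expand_matrix(c("P1", "P2"), "c")
  expect_equal(sp[order(sp$from), ], mx[order(mx$from), ])
})

test_that("the four views conserve labeled edges and order node counts", {
  cat <- complex_catalog(c("c1", "c2", "c3"),
                         list(c("H", "A", "B"), c("H", "C", "D"),
                              c("H", "A", "E")),
                         bait = c("H", "H", "H"))
  views <- lapply(c("multiedge", "multihub", "multinode"),
                  function(v) build_view(cat, "spoke", v))
  ec <- vapply(views, igraph::ecount, 1)
  expect_true(all(ec == ec[1]))               # edge-count conservation
  vc <- vapply(views, igraph::vcount, 1)
  expect_true(vc[1] <= vc[2] && vc[2] <= vc[3])
  # the shared hub carries one parallel bundle per complex in multiedge
  me <- views[[1]]
  expect_equal(sum(igraph::E(me)$complex_id == "c1"), 2L)
  deg_H <- igraph::degree(me)[["H"]]
  expect_equal(deg_H, 6L)                     # 2 edges per complex at hub
  # multinode: one component per complex
  expect_equal(igraph::components(views[[3]])$no, 3L)
  # multihub splits only the hub
  mh <- views[[2]]
  expect_equal(sum(grepl("@", igraph::V(mh)$name)), 3L)
  expect_error(build_view(cat, "matrix", "multihub"), "hub")
})

test_that("two nested spoke complexes with a shared hub duplicate the common edge", {
  cat <- complex_catalog(c("c1", "c2"),
                         list(c("P1", "P2", "P3"), c("P1", "P2")),
                         bait = c("P1", "P1"))
  g <- build_view(cat, "spoke", "multiedge")
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 3L)
  el <- igraph::as_edgelist(g)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  expect_equal(sum(key == "P1 P2"), 2L)       # duplicated under two labels
  expect_setequal(igraph::E(g)$complex_id[key == "P1 P2"], c("c1", "c2"))
})

test_that("collapsing the multinode view reproduces the node-attribute graph", {
  cat <- random_catalog(12, seed = 5)
  cat$bait <- vapply(cat$members, function(m) sort(m)[1], "")
  mn <- build_view(cat, "spoke", "multinode")
  na_view <- build_view(cat, "spoke", "node_attribute")
  # collapse: strip the @complex suffix, merge parallel edges
  el <- igraph::as_edgelist(mn)
  el <- cbind(sub("@.*$", "", el[, 1]), sub("@.*$", "", el[, 2]))
  key <- unique(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  el2 <- igraph::as_edgelist(na_view)
  key2 <- paste(pmin(el2[, 1], el2[, 2]), pmax(el2[, 1], el2[, 2]))
  expect_setequal(key, key2)
  # node_attribute view is simple and carries complex sets on nodes
  expect_false(igraph::any_multiple(na_view))
  cplx_P <- strsplit(igraph::V(na_view)$complexes[1], "|", fixed = TRUE)[[1]]
  p <- igraph::V(na_view)$name[1]
  expect_setequal(cplx_P, cat$complex_id[vapply(cat$members,
                                                function(m) p %in% m, TRUE)])
})

test_that("subcomplex spoke edges nest under a shared hub but not otherwise", {
  maximal <- c("H", "A", "B", "C")
  sub <- c("H", "A", "B")
  pair_keys <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  # same hub: subcomplex edges are a subset of the maximal complex's edges
  e_max <- expand_spoke(maximal, "cmax", bait = "H")
  e_sub <- expand_spoke(sub, "csub", bait = "H")
  expect_true(all(pair_keys(e_sub) %in% pair_keys(e_max)))
  # different hub: containment fails (the representation artifact)
  e_sub2 <- expand_spoke(sub, "csub", bait = "B")
  expect_false(all(pair_keys(e_sub2) %in% pair_keys(e_max)))
})

test_that("GraphML export round-trips the labeled edge multiset", {
  cat <- complex_catalog(c("c1", "c2"),
                         list(c("P1", "P2", "P3"), c("P1", "P2")),
                         bait = c("P1", "P1"))
  g <- build_view(cat, "spoke", "multiedge")
  tf <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(g, tf)
  back <- import_graphml(tf)
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  lab <- function(gr) {
    el <- igraph::as_edgelist(gr)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
               igraph::E(gr)$complex_id))
  }
  expect_equal(lab(back), lab(g))
  # empty graph stays valid
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  export_graphml(empty, tf)
  expect_equal(igraph::vcount(import_graphml(tf)), 0L)
})
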