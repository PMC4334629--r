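test_that("HAT complexes yield five nested pairs and two overlapping groups", {
  cat <- hat_catalog()
  pairs <- find_nested_pairs(all_pairs(cat), cat)
  expect_equal(nrow(pairs), 5L)
  got <- paste(pairs$maximal_id, pairs$sub_id)
  expect_setequal(got, c("SAGA SALSA", "SAGA ADA_GCN5", "SALSA ADA_GCN5",
                         "SLIK SALSA", "SLIK ADA_GCN5"))
  groups <- nested_groups(pairs, cat)
  expect_length(groups, 2L)
  keys <- group_keys(groups)
  expect_equal(keys, sort(c("ADA_GCN5,SAGA,SALSA", "ADA_GCN5,SALSA,SLIK")))
  # the two subcomplexes are shared between both groups
  in_both <- Reduce(intersect, lapply(groups, function(g) g$members))
  expect_setequal(in_both, c("SALSA", "ADA_GCN5"))
})

test_that("nested pairs orient the larger complex first", {
  cat <- catalog_subset(mips_catalog(), c("TIM22_complex", "TIM9_TIM10"))
  pairs <- find_nested_pairs(all_pairs(cat), cat)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$maximal_id, "TIM22_complex")
  expect_equal(pairs$sub_id, "TIM9_TIM10")
  # disjoint complexes: no pairs, no groups
  cat2 <- complex_catalog(c("a", "b"), list(c("P1", "P2"), c("P3", "P4")))
  p2 <- find_nested_pairs(all_pairs(cat2), cat2)
  expect_equal(nrow(p2), 0L)
  expect_length(nested_groups(p2, cat2), 0L)
})

test_that("equal member sets are refused with a dedupe hint", {
  cat <- complex_catalog(c("c1", "c2"),
                         list(c("P1", "P2"), c("P2", "P1")))
  expect_error(find_nested_pairs(all_pairs(cat), cat), "dedupe")
})

test_that("a nested chain forms one group rooted at the top", {
  cat <- complex_catalog(c("A", "B", "C"),
                         list(c("P1", "P2", "P3", "P4"),
                              c("P1", "P2", "P3"), c("P1", "P2")))
  pairs <- find_nested_pairs(all_pairs(cat), cat)
  expect_equal(nrow(pairs), 3L)  # A>B, A>C, B>C
  groups <- nested_groups(pairs, cat)
  expect_length(groups, 1L)
  expect_equal(groups[[1]]$root, "A")
  expect_setequal(groups[[1]]$members, c("A", "B", "C"))
})

test_that("DAG+DFS groups equal the brute-force subset definition", {
  for (seed in 1:5) {
    cat <- random_catalog(50, n_proteins = 25, seed = seed, p_subset = 0.4)
    dd <- dedupe_catalog(cat)$catalog
    groups <- nested_groups(find_nested_pairs(all_pairs(dd), dd), dd)
    expect_equal(group_keys(groups), group_keys(bf_nested_groups(dd)))
    # structural invariants
    for (g in groups) {
      expect_gte(g$size, 2L)
      root_set <- dd$members[[g$root]]
      for (s in setdiff(g$members, g$root)) {
        expect_true(all(dd$members[[s]] %in% root_set))
        expect_lt(length(dd$members[[s]]), length(root_set))
      }
    }
  }
})

test_that("merge_overlapping collapses root-sharing groups", {
  cat <- hat_catalog()
  pairs <- find_nested_pairs(all_pairs(cat), cat)
  merged <- nested_groups(pairs, cat, merge_overlapping = TRUE)
  expect_length(merged, 1L)
  expect_setequal(merged[[1]]$root, c("SAGA", "SLIK"))
  expect_setequal(merged[[1]]$members,
                  c("SAGA", "SLIK", "SALSA", "ADA_GCN5"))
})

test_that("reliable-set filter removes suspect size-2 groups only", {
  cat <- complex_catalog(
    c("big", "dup", "small", "other"),
    list(sprintf("P%02d", 1:10), sprintf("P%02d", 1:9),
         sprintf("P%02d", 1:4), c("Q1", "Q2")),
    pub_id = c("pm1", "pm2", "pm1", "pm1"),
    source_db = c("dbA", "dbB", "dbA", "dbA"))
  pairs <- find_nested_pairs(all_pairs(cat), cat)
  groups <- nested_groups(pairs, cat)
  expect_length(groups, 1L)                   # big > {dup, small}
  # size-3 group is kept but its high-Jaccard pair is flagged
  rel <- filter_reliable(groups, pairs)
  expect_length(rel, 1L)
  expect_equal(rel[[1]]$flagged_pairs$to, "dup")   # jaccard 0.9 > 0.85
  # size-2 group above the threshold is dropped
  cat2 <- catalog_subset(cat, c("big", "dup"))
  p2 <- find_nested_pairs(all_pairs(cat2), cat2)
  g2 <- nested_groups(p2, cat2)
  expect_length(filter_reliable(g2, p2), 0L)
  expect_length(filter_reliable(g2, p2, jaccard_threshold = 1), 1L)
  expect_length(filter_reliable(g2, p2, direction = "exclude_below"), 1L)
  # low-Jaccard size-2 group is retained under the default
  cat3 <- complex_catalog(c("c1", "c2"),
                          list(sprintf("P%02d", 1:10), c("P01", "P02")))
  p3 <- find_nested_pairs(all_pairs(cat3), cat3)
  expect_length(filter_reliable(nested_groups(p3, cat3), p3), 1L)
})

test_that("shared/nonshared partition matches printed subunit lists", {
  cat <- hat_catalog()
  groups <- nested_groups(find_nested_pairs(all_pairs(cat), cat), cat)
  saga <- groups[[which(vapply(groups, function(g) g$root, "") == "SAGA")]]
  p <- shared_partition(saga, cat)
  expect_setequal(p$shared, cat$members$SALSA)  # 11 acetylation-core subunits
  expect_setequal(p$nonshared,
                  c("CHD1", "SGF11", "SGF29", "SGF73", "SPT8", "SUS1",
                    "TAF10", "TAF9", "UBP8"))
  expect_setequal(c(p$shared, p$nonshared), cat$members$SAGA)
  expect_length(intersect(p$shared, p$nonshared), 0L)

  mips <- catalog_subset(mips_catalog(), c("TIM22_complex", "TIM9_TIM10"))
  g <- nested_groups(find_nested_pairs(all_pairs(mips), mips), mips)
  p <- shared_partition(g[[1]], mips)
  expect_setequal(p$shared, c("TIM9", "TIM10"))
  expect_setequal(p$nonshared, c("TIM12", "TIM22", "TIM54"))

  # sub = root minus one protein: exactly one nonshared protein
  cat2 <- complex_catalog(c("r", "s"),
                          list(c("P1", "P2", "P3"), c("P1", "P2")))
  g2 <- nested_groups(find_nested_pairs(all_pairs(cat2), cat2), cat2)
  expect_length(shared_partition(g2[[1]], cat2)$nonshared, 1L)
})

test_that("provenance flags same-source and multi-source groups", {
  cat <- complex_catalog(
    c("r", "s1", "s2", "x", "y"),
    list(c("P1", "P2", "P3", "P4"), c("P1", "P2"), c("P2", "P3"),
         c("Q1", "Q2", "Q3"), c("Q1", "Q2")),
    pub_id = c("pm1", "pm1", "pm1", "pm1", "pm2"),
    source_db = c("dbA", "dbA", "dbA", "dbA", "dbA"))
  groups <- nested_groups(find_nested_pairs(all_pairs(cat), cat), cat)
  prov <- provenance_analysis(groups, cat)
  pg <- prov$per_group
  roots <- vapply(groups, function(g) g$root, "")
  expect_true(pg$same_source[pg$group_id ==
                               groups[[which(roots == "r")]]$group_id])
  # different papers, same database: multi-source size-2 group
  expect_false(pg$same_source[pg$group_id ==
                                groups[[which(roots == "x")]]$group_id])
  expect_equal(sum(prov$size2$total_count), 1L)
  expect_equal(sum(prov$size2$multisource_count), 1L)
})
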