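# Independent oracles and fixture builders used across the suite.
# Every oracle deliberately takes the naive route (quadratic scans,
# exhaustive enumeration) so it shares no code path with the package.

hat_catalog <- function() {
  path <- system.file("extdata", "mips_worked_examples.tsv",
                      package = "complexnest")
  catalog_subset(read_catalog_tsv(path),
                 c("SAGA", "SALSA", "SLIK", "ADA_GCN5"))
}

mips_catalog <- function() {
  read_catalog_tsv(system.file("extdata", "mips_worked_examples.tsv",
                               package = "complexnest"))
}

# random catalog with deliberate nesting and duplicates for property tests
random_catalog <- function(n, n_proteins = 40, seed = 1,
                           p_subset = 0.3, p_dup = 0) {
  set.seed(seed)
  universe <- sprintf("U%03d", seq_len(n_proteins))
  members <- list()
  for (i in seq_len(n)) {
    if (length(members) && stats::runif(1) < p_subset) {
      parent <- members[[sample(length(members), 1)]]
      k <- sample(max(1, length(parent) - 1), 1)
      members[[i]] <- sample(parent, max(2, min(k, length(parent))))
    } else if (length(members) && stats::runif(1) < p_dup) {
      members[[i]] <- members[[sample(length(members), 1)]]
    } else {
      members[[i]] <- sample(universe, sample(2:8, 1))
    }
  }
  complex_catalog(sprintf("r%03d", seq_len(n)), members,
                  pub_id = sample(c("pmA", "pmB"), n, replace = TRUE),
                  source_db = sample(c("db1", "db2"), n, replace = TRUE))
}

# O(n^2) all-pairs scan
bf_all_pairs <- function(catalog) {
  n <- length(catalog)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ps <- pair_score(catalog$members[[i]], catalog$members[[j]])
    if (ps$intersection > 0) {
      ids <- sort(c(catalog$complex_id[i], catalog$complex_id[j]))
      rows[[length(rows) + 1]] <- data.frame(
        id_a = ids[1], id_b = ids[2], intersection = ps$intersection,
        meet_min = ps$meet_min, jaccard = ps$jaccard,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_a = character(0), id_b = character(0),
               intersection = integer(0), meet_min = numeric(0),
               jaccard = numeric(0))
  df[order(df$id_a, df$id_b), , drop = FALSE]
}

# brute-force nested groups straight from the definition: every complex
# with no strict superset and at least one strict subset founds a group of
# itself plus all its strict subsets
bf_nested_groups <- function(catalog) {
  m <- catalog$members
  ids <- catalog$complex_id
  strict_subset <- function(a, b) length(a) < length(b) && all(a %in% b)
  out <- list()
  for (r in ids) {
    has_super <- any(vapply(ids, function(o)
      o != r && strict_subset(m[[r]], m[[o]]), TRUE))
    if (has_super) next
    subs <- ids[vapply(ids, function(o)
      o != r && strict_subset(m[[o]], m[[r]]), TRUE)]
    if (length(subs)) out[[length(out) + 1]] <- sort(c(r, subs))
  }
  out
}

group_keys <- function(groups) {
  sort(vapply(groups, function(g) {
    ids <- if (is.list(g)) g$members else g
    paste(sort(ids), collapse = ",")
  }, ""))
}

# exhaustive urn enumeration of the hypergeometric upper tail
bf_hypergeom_upper <- function(population, successes, sample_size, observed) {
  urn <- c(rep(1, successes), rep(0, population - successes))
  combos <- utils::combn(population, sample_size)
  hits <- apply(combos, 2, function(idx) sum(urn[idx]) >= observed)
  mean(hits)
}

# exact two-sided rank-sum p by enumerating all rank assignments
bf_ranksum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# modularity by edge-by-edge accumulation
bf_modularity <- function(graph, partition) {
  el <- igraph::as_edgelist(graph)
  m <- nrow(el)
  if (m == 0) return(NA_real_)
  comm <- partition
  intra <- 0
  deg_sum <- numeric(0)
  for (e in seq_len(m)) {
    cu <- comm[[el[e, 1]]]; cv <- comm[[el[e, 2]]]
    if (cu == cv) intra <- intra + 1
    deg_sum[as.character(cu)] <- sum(deg_sum[as.character(cu)], 1, na.rm = TRUE)
    deg_sum[as.character(cv)] <- sum(deg_sum[as.character(cv)], 1, na.rm = TRUE)
  }
  # isolated nodes contribute degree 0; their communities add 0 terms
  intra / m - sum((deg_sum / (2 * m))^2)
}

# brute-force motif census: all node subsets, connectivity filter, classes
# discovered by pairwise isomorphism against the package class catalog
bf_motif_census <- function(graph, sizes = 3:5) {
  cls <- motif_classes()
  reps <- lapply(seq_len(nrow(cls)), function(i) {
    el <- do.call(rbind, lapply(strsplit(cls$edge_list[i], ";")[[1]],
                                function(s) as.integer(strsplit(s, "-")[[1]])))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::add_vertices(g, cls$size[i] - igraph::vcount(g))
  })
  counts <- stats::setNames(rep(0L, nrow(cls)), cls$class_id)
  nodes <- igraph::V(graph)$name
  for (k in sizes) {
    if (length(nodes) < k) next
    combos <- utils::combn(nodes, k)
    for (c_i in seq_len(ncol(combos))) {
      sub <- igraph::induced_subgraph(graph, combos[, c_i])
      if (!igraph::is_connected(sub)) next
      hit <- which(cls$size == k &
                     cls$n_edges == igraph::ecount(sub))
      for (h in hit) {
        if (igraph::isomorphic(sub, reps[[h]])) {
          counts[h] <- counts[h] + 1L
          break
        }
      }
    }
  }
  counts
}

# random simple graph with given edge probability, named nodes
random_graph <- function(n, p, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}
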