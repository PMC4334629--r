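#' Community detection on a group subgraph
#'
#' Runs one of three standard community detection algorithms on the simple
#' projection of a nested-group subgraph. Edge-betweenness communities are
#' cut at the dendrogram level of maximum modularity; walktrap uses random
#' walks of length 4 (its authors' default); label propagation is
#' stochastic and is seeded for reproducibility.
#'
#' @param graph an igraph object (simple projection used internally).
#' @param algorithm `"edge_betweenness"`, `"walktrap"` or
#'   `"label_propagation"`.
#' @param seed integer seed (label propagation).
#' @return named integer vector node -> community id (empty for an empty
#'   graph).
#' @export
detect_communities <- function(graph,
                               algorithm = c("edge_betweenness", "walktrap",
                                             "label_propagation"),
                               seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (igraph::vcount(graph) == 0L) return(stats::setNames(integer(0), character(0)))
  sp <- if (igraph::any_multiple(graph)) simple_projection(graph) else
    igraph::simplify(graph)
  set.seed(seed)
  cm <- switch(algorithm,
    edge_betweenness = suppressWarnings(
      igraph::cluster_edge_betweenness(sp, weights = NULL)),
    walktrap = igraph::cluster_walktrap(sp, steps = 4),
    label_propagation = igraph::cluster_label_prop(sp))
  stats::setNames(igraph::membership(cm), igraph::V(sp)$name)
}

#' Newman-Girvan modularity
#'
#' Q = sum over communities c of (e_c / m - (d_c / 2m)^2), where m is the
#' total edge count, e_c the number of intra-community edges and d_c the
#' sum of degrees of the community's nodes. Computed directly from the
#' formula (independent of igraph's implementation, which serves as a
#' cross-check in the test suite). Undefined (NA) for edgeless graphs.
#'
#' @param graph an igraph object (simple graph expected).
#' @param partition named vector node -> community covering all nodes.
#' @return a single numeric Q, or `NA` when the graph has no edges.
#' @export
newman_girvan_modularity <- function(graph, partition) {
  sp <- if (igraph::any_multiple(graph)) simple_projection(graph) else graph
  nodes <- igraph::V(sp)$name
  if (!all(nodes %in% names(partition)))
    stop("partition must cover all nodes")
  m <- igraph::ecount(sp)
  if (m == 0L) return(NA_real_)
  el <- igraph::as_edgelist(sp)
  comm <- partition[nodes]
  deg <- igraph::degree(sp)
  q <- 0
  for (cid in unique(comm)) {
    in_c <- names(comm)[comm == cid]
    e_c <- sum(el[, 1] %in% in_c & el[, 2] %in% in_c)
    d_c <- sum(deg[in_c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Evaluate a community partition as a subcomplex predictor
#'
#' Treats each detected community as a predicted subcomplex of a nested
#' group and scores it against the group's known subcomplexes: a community
#' is a true positive when its node set matches some subcomplex's member
#' set at Jaccard >= `match_threshold` (greedy one-to-one matching by
#' descending Jaccard, so each subcomplex is matched at most once);
#' unmatched communities are false positives, unmatched subcomplexes false
#' negatives. Precision = TP / (TP + FP), FDR = FP / (TP + FP).
#'
#' @param partition named vector node -> community.
#' @param group one element of a `nested_groups` object.
#' @param catalog the `complex_catalog`.
#' @param match_threshold Jaccard threshold (default 0.5); use 1 for
#'   exact-match mode.
#' @return list with `tp`, `fp`, `fn`, `precision`, `fdr` (the last two
#'   `NA` when no community was predicted).
#' @export
evaluate_as_predictor <- function(partition, group, catalog,
                                  match_threshold = 0.5) {
  subs <- setdiff(group$members, group$root)
  if (!length(subs)) stop("group has no subcomplex to predict")
  sub_sets <- catalog$members[subs]
  comm_sets <- split(names(partition), partition)
  if (!length(comm_sets))
    return(list(tp = 0L, fp = 0L, fn = length(subs),
                precision = NA_real_, fdr = NA_real_))
  jac <- function(a, b) {
    i <- length(intersect(a, b)); i / (length(a) + length(b) - i)
  }
  cand <- expand.grid(ci = seq_along(comm_sets), si = seq_along(sub_sets))
  cand$j <- mapply(function(ci, si) jac(comm_sets[[ci]], sub_sets[[si]]),
                   cand$ci, cand$si)
  cand <- cand[cand$j >= match_threshold, , drop = FALSE]
  cand <- cand[order(-cand$j, cand$ci, cand$si), , drop = FALSE]
  used_c <- logical(length(comm_sets)); used_s <- logical(length(sub_sets))
  tp <- 0L
  for (r in seq_len(nrow(cand))) {
    ci <- cand$ci[r]; si <- cand$si[r]
    if (used_c[ci] || used_s[si]) next
    used_c[ci] <- TRUE; used_s[si] <- TRUE
    tp <- tp + 1L
  }
  fp <- length(comm_sets) - tp
  fn <- length(sub_sets) - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = tp / (tp + fp), fdr = fp / (tp + fp))
}

#' Modularity evaluation of all nested groups
#'
#' For every nested group: induce the group's subgraph from the
#' protein-level graph, detect communities, compute Newman-Girvan
#' modularity, and score the communities as subcomplex predictors.
#'
#' @param groups a `nested_groups` object.
#' @param catalog the `complex_catalog`.
#' @param graph the protein-level multiedge graph of the catalog.
#' @param algorithm passed to [detect_communities()].
#' @param match_threshold passed to [evaluate_as_predictor()].
#' @param seed integer seed.
#' @return data.frame with one row per group: `group_id`, `algorithm`,
#'   `n_communities`, `modularity`, `tp`, `fp`, `fn`, `precision`, `fdr`.
#' @export
modularity_eval <- function(groups, catalog, graph,
                            algorithm = "edge_betweenness",
                            match_threshold = 0.5, seed = 1L) {
  rows <- lapply(groups, function(gr) {
    prot <- unique(unlist(catalog$members[gr$members], use.names = FALSE))
    sub <- igraph::induced_subgraph(graph, prot)
    part <- detect_communities(sub, algorithm, seed = seed)
    q <- newman_girvan_modularity(sub, part)
    ev <- evaluate_as_predictor(part, gr, catalog, match_threshold)
    data.frame(group_id = gr$group_id, algorithm = algorithm,
               n_communities = length(unique(part)), modularity = q,
               tp = ev$tp, fp = ev$fp, fn = ev$fn,
               precision = ev$precision, fdr = ev$fdr,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_id = character(0), algorithm = character(0),
               n_communities = integer(0), modularity = numeric(0),
               tp = integer(0), fp = integer(0), fn = integer(0),
               precision = numeric(0), fdr = numeric(0))
  rownames(out) <- NULL
  out
}
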