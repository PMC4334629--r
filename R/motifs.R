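# Motif census of connected undirected subgraphs on 3-5 nodes.
#
# Classes are built once by enumerating all edge subsets on k labeled
# nodes, keeping connected graphs, and collapsing isomorphs via canonical
# labeling. Individual subgraphs are then classified by the pair (sorted
# degree sequence, triangle count), which is verified at catalog-build
# time to be collision-free for connected graphs on <= 5 nodes.

.motif_env <- new.env(parent = emptyenv())

motif_invariant <- function(A) {
  tri <- sum(diag(A %*% A %*% A)) / 6
  paste(nrow(A), paste(sort(colSums(A)), collapse = ""), tri, sep = "|")
}

#' Catalog of connected motif classes on 3-5 nodes
#'
#' Enumerates, once per session, the isomorphism classes of connected
#' undirected graphs on 3, 4 and 5 nodes (2, 6 and 21 classes) and names
#' them `s<k>.e<m>.<i>` (size, edge count, index within). The canonical
#' edge list documents each class.
#'
#' @return data.frame with `class_id`, `size`, `n_edges`, `edge_list`
#'   (canonical, semicolon-separated `a-b` pairs) and the internal
#'   `invariant` key.
#' @export
motif_classes <- function() {
  if (!is.null(.motif_env$classes)) return(.motif_env$classes)
  rows <- list()
  for (k in 3:5) {
    pairs <- utils::combn(k, 2L)
    np <- ncol(pairs)
    seen <- character(0)
    for (mask in 0:(2^np - 1L)) {
      sel <- which(bitwAnd(mask, 2^(0:(np - 1L))) > 0)
      A <- matrix(0L, k, k)
      for (s in sel) {
        A[pairs[1, s], pairs[2, s]] <- 1L
        A[pairs[2, s], pairs[1, s]] <- 1L
      }
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      if (!igraph::is_connected(g)) next
      cp <- igraph::canonical_permutation(g)$labeling
      h <- igraph::permute(g, cp)
      el <- igraph::as_edgelist(h)
      el <- el[order(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), ,
               drop = FALSE]
      key <- paste(paste(pmin(el[, 1], el[, 2]),
                         pmax(el[, 1], el[, 2]), sep = "-"),
                   collapse = ";")
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- data.frame(
        size = k, n_edges = length(sel), edge_list = key,
        invariant = motif_invariant(A), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$size, df$n_edges, df$edge_list), , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(df)),
                    paste(df$size, df$n_edges), FUN = seq_along)
  df$class_id <- sprintf("s%d.e%d.%d", df$size, df$n_edges, idx)
  if (anyDuplicated(df$invariant))
    stop("internal error: motif invariant collision")  # never for n <= 5
  df <- df[c("class_id", "size", "n_edges", "edge_list", "invariant")]
  rownames(df) <- NULL
  .motif_env$classes <- df
  df
}

# ESU enumeration of connected induced k-subgraphs; calls `record(nodes)`
# once per subgraph.
esu_enumerate <- function(adj, k, record) {
  n <- length(adj)
  extend <- function(sub, ext, v) {
    if (length(sub) == k) { record(sub); return(invisible()) }
    nsub_mask <- rep(FALSE, n)
    nsub_mask[unlist(adj[sub], use.names = FALSE)] <- TRUE
    nsub_mask[sub] <- TRUE
    while (length(ext)) {
      w <- ext[1L]; ext <- ext[-1L]
      excl <- adj[[w]]
      excl <- excl[excl > v & !nsub_mask[excl]]
      extend(c(sub, w), c(ext, setdiff(excl, ext)), v)
    }
  }
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    extend(v, nb[nb > v], v)
  }
}

#' Motif census of a graph
#'
#' Counts the connected induced subgraphs on 3, 4 and 5 nodes of the
#' simple projection of a (group sub)graph, classified up to isomorphism.
#' Enumeration uses the ESU algorithm, so each induced subgraph is visited
#' exactly once. Graphs above the node budget are skipped (the number of
#' 5-subsets explodes; nested-group subgraphs are small in practice).
#'
#' @param graph an igraph object (projected to a simple graph internally).
#' @param sizes subset of `c(3, 4, 5)`.
#' @param node_budget skip (with a warning) graphs with more nodes.
#' @return data.frame with one row per motif class of the requested sizes:
#'   `class_id`, `size`, `n_edges`, `count` (zero-count classes included),
#'   or `NULL` when the budget is exceeded.
#' @export
motif_census <- function(graph, sizes = c(3L, 4L, 5L), node_budget = 200L) {
  stopifnot(all(sizes %in% 3:5))
  if (igraph::vcount(graph) > node_budget) {
    warning("graph has ", igraph::vcount(graph), " nodes (budget ",
            node_budget, "); motif census skipped")
    return(NULL)
  }
  sp <- if (igraph::any_multiple(graph)) simple_projection(graph) else
    igraph::simplify(graph)
  cls <- motif_classes()
  cls <- cls[cls$size %in% sizes, , drop = FALSE]
  counts <- stats::setNames(rep(0L, nrow(cls)), cls$invariant)
  A <- as.matrix(igraph::as_adjacency_matrix(sp))
  adj <- lapply(seq_len(nrow(A)), function(i) which(A[i, ] > 0))
  for (k in sizes) {
    esu_enumerate(adj, k, function(nodes) {
      inv <- motif_invariant(A[nodes, nodes, drop = FALSE])
      counts[inv] <<- counts[inv] + 1L
    })
  }
  data.frame(class_id = cls$class_id, size = cls$size,
             n_edges = cls$n_edges, count = unname(counts[cls$invariant]),
             stringsAsFactors = FALSE)
}

#' Motif significance against a degree-preserving null
#'
#' Compares the observed census to `n_random` rewired replicas of the
#' graph. Each replica is produced by degree-preserving edge swaps
#' (`swap_factor * |E|` attempted swaps), so the degree sequence is exactly
#' conserved while the wiring is randomized. Per class: z-score
#' (obs - null mean) / null sd (0 when the null is degenerate at the
#' observed value) and the empirical upper-tail p-value
#' (1 + #\{null >= obs\}) / (n_random + 1). Classes with p <= alpha count
#' as significant.
#'
#' @param graph the graph the census came from.
#' @param census data.frame from [motif_census()].
#' @param n_random number of rewired replicas (default 100).
#' @param seed integer seed.
#' @param swap_factor attempted swaps per edge (default 100).
#' @param alpha significance level (default 0.05).
#' @param sizes motif sizes (must match the census).
#' @return list with `census` (the input plus `null_mean`, `null_sd`, `z`,
#'   `p_emp`, `significant`), `n_motifs` (total observed count) and
#'   `n_significant` (observed count in significant classes).
#' @export
motif_significance <- function(graph, census, n_random = 100L, seed = 1L,
                               swap_factor = 100L, alpha = 0.05,
                               sizes = c(3L, 4L, 5L)) {
  if (is.null(census)) return(NULL)
  sp <- if (igraph::any_multiple(graph)) simple_projection(graph) else
    igraph::simplify(graph)
  set.seed(seed)
  nulls <- matrix(0L, nrow = n_random, ncol = nrow(census))
  deg0 <- sort(igraph::degree(sp))
  for (r in seq_len(n_random)) {
    gr <- if (swap_factor > 0L && igraph::ecount(sp) >= 2L)
      igraph::rewire(sp, igraph::keeping_degseq(
        loops = FALSE, niter = max(1L, swap_factor * igraph::ecount(sp))))
    else sp
    stopifnot(identical(sort(igraph::degree(gr)), deg0))
    nulls[r, ] <- motif_census(gr, sizes = sizes)$count
  }
  if (n_random > 0L) {
    mu <- colMeans(nulls)
    sdv <- apply(nulls, 2, stats::sd)
    ge <- vapply(seq_len(nrow(census)),
                 function(j) sum(nulls[, j] >= census$count[j]), 1L)
    p <- (1 + ge) / (n_random + 1)
  } else {
    mu <- census$count; sdv <- rep(0, nrow(census)); p <- rep(1, nrow(census))
  }
  z <- ifelse(sdv > 0, (census$count - mu) / sdv, 0)
  out <- census
  out$null_mean <- mu; out$null_sd <- sdv; out$z <- z; out$p_emp <- p
  out$significant <- out$count > 0L & p <= alpha
  list(census = out, n_motifs = sum(out$count),
       n_significant = sum(out$count[out$significant]))
}

#' Imperfect 5-clique summary
#'
#' Annotates every 5-node motif class with its number of missing edges
#' m = 10 - |edges| relative to the complete graph on 5 nodes, and
#' summarizes the observed 5-node motifs as a histogram of m. m = 0 is the
#' perfect 5-clique; 1 <= m <= 7 are the imperfect 5-cliques that arise
#' when a subcomplex is spoke-expanded with a different hub than its
#' maximal complex.
#'
#' @param census a census data.frame (or the `census` element of
#'   [motif_significance()] output) containing size-5 classes.
#' @return list with `classes` (size-5 rows plus `missing_edges`),
#'   `missing_histogram` (data.frame `missing_edges`, `count` over observed
#'   motifs) and `dominant_class` (class_id with the highest observed
#'   count, `NA` if none observed).
#' @export
imperfect_5clique_summary <- function(census) {
  c5 <- census[census$size == 5L, , drop = FALSE]
  if (!nrow(c5)) stop("census contains no size-5 classes")
  c5$missing_edges <- 10L - c5$n_edges
  hist <- stats::aggregate(count ~ missing_edges, data = c5, FUN = sum)
  names(hist) <- c("missing_edges", "count")
  dom <- if (sum(c5$count)) c5$class_id[which.max(c5$count)] else NA_character_
  list(classes = c5, missing_histogram = hist, dominant_class = dom)
}
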