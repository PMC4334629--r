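#' Node metrics on the multiedge graph
#'
#' Computes, per protein, the four metrics used to contrast shared and
#' nonshared proteins. The multiedge graph has no single canonical metric
#' contract, so each metric uses its most standard multigraph reading:
#' \itemize{
#'   \item degree counts parallel edges (membership in several complexes
#'     inflates degree, by design);
#'   \item PageRank runs on the simple projection with edge weight =
#'     multiplicity (a random walker follows parallel edges
#'     proportionally); damping 0.85;
#'   \item betweenness runs on the unweighted simple projection by default
#'     (igraph edge weights are distances, so using multiplicity as a
#'     weight would push shortest paths away from multi-complex pairs —
#'     the opposite of the intended emphasis); raw, unnormalized path
#'     counts; `betweenness_weights = "inverse_multiplicity"` makes
#'     multi-complex pairs shorter instead;
#'   \item the local clustering coefficient uses the unweighted simple
#'     projection, with nodes of degree < 2 assigned 0.
#' }
#'
#' @param graph a multiedge igraph from [build_view()].
#' @param damping PageRank damping factor.
#' @param betweenness_weights `"none"` (default) or
#'   `"inverse_multiplicity"`.
#' @return data.frame with columns `protein`, `degree`, `betweenness`,
#'   `pagerank`, `local_clustering`.
#' @export
node_metrics <- function(graph, damping = 0.85,
                         betweenness_weights = c("none",
                                                 "inverse_multiplicity")) {
  betweenness_weights <- match.arg(betweenness_weights)
  if (igraph::vcount(graph) == 0L)
    return(data.frame(protein = character(0), degree = integer(0),
                      betweenness = numeric(0), pagerank = numeric(0),
                      local_clustering = numeric(0)))
  sp <- simple_projection(graph)
  bw_w <- if (betweenness_weights == "none") NA else
    1 / igraph::E(sp)$multiplicity
  btw <- igraph::betweenness(sp, weights = bw_w, normalized = FALSE)
  pr <- igraph::page_rank(sp, damping = damping,
                          weights = igraph::E(sp)$multiplicity)$vector
  cc <- igraph::transitivity(sp, type = "local", isolates = "zero")
  names(cc) <- igraph::V(sp)$name
  cc <- cc[igraph::V(graph)$name]
  data.frame(protein = igraph::V(graph)$name,
             degree = igraph::degree(graph),
             betweenness = btw[igraph::V(graph)$name],
             pagerank = pr[igraph::V(graph)$name],
             local_clustering = cc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Global clustering coefficient
#'
#' Number of closed triplets over the total number of triplets (3 times
#' the triangle count over the number of connected triples), computed on
#' the simple projection. 0 when the graph has no connected triple.
#'
#' @param graph an igraph object (multiedge graphs are projected first).
#' @return a single numeric value.
#' @export
global_clustering <- function(graph) {
  sp <- if (igraph::any_multiple(graph)) simple_projection(graph) else graph
  v <- igraph::transitivity(sp, type = "global")
  if (is.nan(v)) 0 else v
}

#' Two-sample rank-sum test
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test of the null that the two
#' samples come from the same distribution. Exact enumeration is used when
#' both samples have at most 8 observations and there are no ties; the
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param sample_a,sample_b numeric vectors (nonempty).
#' @return list with `p_value` and `statistic` (the Mann-Whitney U of
#'   sample_a).
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be nonempty")
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0L
  exact <- !ties && length(sample_a) <= 8L && length(sample_b) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  p <- wt$p.value
  # complete ties degenerate the normal approximation (sd = 0): no rank
  # separation means no evidence against the null
  if (is.nan(p)) p <- 1
  list(p_value = p, statistic = unname(wt$statistic))
}

#' Compare metrics between shared and nonshared proteins
#'
#' For each of the four node metrics, compares the shared-class values to
#' the nonshared-class values with a two-sided rank-sum test and reports
#' class means plus the class of the top-ranked protein for that metric.
#'
#' @param metrics data.frame from [node_metrics()].
#' @param class named character vector (`shared` / `nonshared` /
#'   `neither`) over proteins, from [classify_proteins()].
#' @return data.frame with one row per metric: `metric`, `mean_shared`,
#'   `mean_nonshared`, `p_value`, `top_protein`, `top_class`,
#'   `computable`.
#' @export
compare_shared_nonshared <- function(metrics, class) {
  cls <- class[metrics$protein]
  out <- lapply(c("degree", "betweenness", "pagerank", "local_clustering"),
                function(m) {
    va <- metrics[[m]][cls == "shared" & !is.na(cls)]
    vb <- metrics[[m]][cls == "nonshared" & !is.na(cls)]
    top <- metrics$protein[which.max(metrics[[m]])]
    if (!length(va) || !length(vb))
      return(data.frame(metric = m, mean_shared = mean(va),
                        mean_nonshared = mean(vb), p_value = NA_real_,
                        top_protein = top,
                        top_class = unname(cls[top]),
                        computable = FALSE, stringsAsFactors = FALSE))
    rs <- rank_sum_test(va, vb)
    data.frame(metric = m, mean_shared = mean(va),
               mean_nonshared = mean(vb), p_value = rs$p_value,
               top_protein = top, top_class = unname(cls[top]),
               computable = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
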