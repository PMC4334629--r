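#' Plot a nested group
#'
#' Draws the paired view of one nested group: the complex plot (the
#' subset DAG, arrows pointing from containing to contained complex) and
#' the protein plot (the group's subgraph of the protein-level network,
#' one edge color per complex).
#'
#' @param x a `nested_groups` object.
#' @param catalog the `complex_catalog`.
#' @param which group index or `group_id` (default: first group).
#' @param model,hub_policy expansion settings for the protein plot.
#' @param ... passed to `plot.igraph`.
#' @return invisibly, `x`.
#' @export
plot.nested_groups <- function(x, catalog, which = 1L, model = "spoke",
                               hub_policy = "bait", ...) {
  if (!length(x)) stop("no groups to plot")
  gr <- if (is.character(which))
    x[[match(which, vapply(x, function(g) g$group_id, ""))]]
  else x[[which]]
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  dag <- igraph::graph_from_data_frame(
    gr$edges, directed = TRUE, vertices = data.frame(name = gr$members))
  plot(dag, main = paste(gr$group_id, "complex plot"),
       vertex.color = ifelse(gr$members %in% gr$root, "tomato", "skyblue"),
       edge.arrow.size = 0.5, ...)
  sub_cat <- catalog_subset(catalog, gr$members)
  pg <- build_view(sub_cat, model = model, view_mode = "multiedge",
                   hub_policy = hub_policy)
  pal <- grDevices::rainbow(length(gr$members))
  names(pal) <- gr$members
  plot(pg, main = paste(gr$group_id, "protein plot"),
       edge.color = pal[igraph::E(pg)$complex_id],
       vertex.size = 12, vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Histogram plots of overlap and nesting distributions
#'
#' Companion plot for [similarity_histograms()]: intersection counts and
#' meet-min distribution side by side.
#'
#' @param histograms output of [similarity_histograms()].
#' @return invisibly, `histograms`.
#' @export
plot_similarity_histograms <- function(histograms) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  with(histograms$intersection,
       graphics::barplot(count, names.arg = value,
                         main = "Overlap distribution",
                         xlab = "intersection size", ylab = "pairs"))
  with(histograms$meet_min,
       graphics::barplot(count, names.arg = sprintf("%.2f", bin_hi),
                         main = "Nesting distribution",
                         xlab = "meet-min (bin upper edge)", ylab = "pairs"))
  invisible(histograms)
}
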