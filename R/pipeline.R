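#' Pipeline configuration
#'
#' Bundles all analysis settings for [run_pipeline()]. Either `catalog_tsv`
#' (+ optional `annotations_tsv`) or a `synthetic_spec` must be supplied.
#' All stochastic stages (Monte Carlo term counts, motif nulls, label
#' propagation, synthetic generation) draw from `seed`.
#'
#' @param catalog_tsv,annotations_tsv input file paths (catalog_io
#'   formats), or `NULL` when `spec` is given.
#' @param spec a `synthetic_spec`, or `NULL` when files are given.
#' @param model,view_mode representation of the protein-level graph.
#' @param hub_policy hub choice for spoke expansion.
#' @param reliable_threshold,reliable_direction reliable-set filter
#'   settings (see [filter_reliable()]); `reliable_threshold = NA`
#'   disables the filter.
#' @param alpha significance level for all tests.
#' @param n_mc Monte Carlo subsamples for GO term counts.
#' @param n_random rewired replicas for motif significance.
#' @param match_threshold community-vs-subcomplex match Jaccard.
#' @param community_algorithm community detection algorithm.
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(catalog_tsv = NULL, annotations_tsv = NULL,
                            spec = NULL, model = "spoke",
                            view_mode = "multiedge", hub_policy = "bait",
                            reliable_threshold = 0.85,
                            reliable_direction = "exclude_above",
                            alpha = 0.05, n_mc = 1000L, n_random = 100L,
                            match_threshold = 0.5,
                            community_algorithm = "edge_betweenness",
                            seed = 1L, out_dir = tempfile("complexnest_run")) {
  if (is.null(catalog_tsv) && is.null(spec))
    stop("either catalog_tsv or a synthetic_spec is required")
  if (!is.na(reliable_threshold) &&
      (reliable_threshold < 0 || reliable_threshold > 1))
    stop("reliable_threshold must lie in [0, 1] (or NA to disable)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full nested-complex analysis pipeline
#'
#' Sequences the stages: catalog input (file or synthetic) ->
#' deduplication -> all-pairs similarity + histograms -> nested pairs and
#' groups (+ reliable-set filter, provenance tables) -> protein-level
#' graph and node metrics with shared/nonshared comparison -> enrichment
#' and GO tables -> motif census and significance -> modularity
#' evaluation -> manifest. Every table is written (TSV/JSON) into
#' `config$out_dir`, even when empty; a stage failure aborts with a
#' stage-named error after writing a `FAILED` marker naming the stage.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) a list with the in-memory results of every stage
#'   and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- list(out_dir = config$out_dir)
  on_fail <- function(e) {
    writeLines(paste("stage:", stage), file.path(config$out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (!is.null(config$spec)) {
      sim <- generate_catalog(config$spec)
      catalog <- sim$catalog; annotations <- sim$annotations
      res$truth <- sim$truth
      write_catalog_tsv(catalog, file.path(config$out_dir, "catalog.tsv"))
      write_annotations_tsv(annotations,
                            file.path(config$out_dir, "annotations.tsv"))
    } else {
      catalog <- read_catalog_tsv(config$catalog_tsv)
      annotations <- if (!is.null(config$annotations_tsv))
        read_annotations_tsv(config$annotations_tsv) else NULL
    }
    dd <- dedupe_catalog(catalog)
    catalog <- dd$catalog
    res$catalog <- catalog; res$annotations <- annotations
    message("input: ", length(catalog), " complexes after dedupe (",
            length(dd$mapping), " merged)")

    stage <- "similarity"
    sim_m <- all_pairs(catalog)
    res$similarity <- sim_m
    write_similarity_tsv(sim_m, file.path(config$out_dir, "similarity.tsv"))
    hist <- similarity_histograms(sim_m)
    write_tsv(hist$intersection, config$out_dir, "hist_intersection.tsv")
    write_tsv(hist$meet_min, config$out_dir, "hist_meet_min.tsv")
    message("similarity: ", nrow(sim_m), " overlapping pairs of ",
            attr(sim_m, "n_possible_pairs"), " possible")

    stage <- "nesting"
    pairs <- find_nested_pairs(sim_m, catalog)
    groups <- nested_groups(pairs, catalog)
    if (!is.na(config$reliable_threshold))
      groups_rel <- filter_reliable(groups, pairs,
                                    config$reliable_threshold,
                                    config$reliable_direction)
    else groups_rel <- groups
    res$pairs <- pairs; res$groups <- groups; res$groups_reliable <- groups_rel
    write_tsv(pairs, config$out_dir, "nested_pairs.tsv")
    write_groups_tsv(groups, file.path(config$out_dir, "nested_groups.tsv"))
    write_groups_json(groups, catalog,
                      file.path(config$out_dir, "nested_groups.json"))
    prov <- provenance_analysis(groups, catalog)
    res$provenance <- prov
    write_tsv(prov$per_group, config$out_dir, "provenance_groups.tsv")
    write_tsv(prov$size2, config$out_dir, "provenance_jaccard.tsv")
    message("nesting: ", nrow(pairs), " nested pairs, ", length(groups),
            " groups (", length(groups_rel), " reliable)")

    stage <- "network_stats"
    graph <- build_view(catalog, model = config$model,
                        view_mode = config$view_mode,
                        hub_policy = config$hub_policy, seed = config$seed)
    res$graph <- graph
    cls <- classify_proteins(groups, catalog)
    res$class <- cls
    metrics <- node_metrics(graph)
    metrics$class <- unname(cls$class[metrics$protein])
    res$metrics <- metrics
    write_tsv(metrics, config$out_dir, "node_metrics.tsv")
    comparison <- compare_shared_nonshared(metrics, cls$class)
    res$comparison <- comparison
    write_tsv(comparison, config$out_dir, "metric_comparison.tsv")
    res$global_clustering <- global_clustering(graph)

    stage <- "enrichment"
    if (!is.null(annotations)) {
      enr <- rbind(cbind(flag = "essential",
                         class_enrichment(cls$class, annotations, "essential")),
                   cbind(flag = "disease",
                         class_enrichment(cls$class, annotations, "disease")))
      res$enrichment <- enr
      write_tsv(enr, config$out_dir, "enrichment.tsv")
      go <- go_counts(cls$class, annotations, n_mc = config$n_mc,
                      seed = config$seed)
      res$go_counts <- go
      write_tsv(go, config$out_dir, "go_counts.tsv")
      homog <- do.call(rbind, lapply(c("BP", "MF", "CC"), function(o) {
        h <- vapply(catalog$complex_id, function(id)
          go_homogeneity(catalog$members[[id]], annotations, o)$homogeneity,
          1)
        data.frame(complex_id = catalog$complex_id, ontology = o,
                   homogeneity = h, stringsAsFactors = FALSE)
      }))
      res$go_homogeneity <- homog
      write_tsv(homog, config$out_dir, "go_homogeneity.tsv")
    } else {
      empty <- data.frame(note = character(0))
      write_tsv(empty, config$out_dir, "enrichment.tsv")
      write_tsv(empty, config$out_dir, "go_counts.tsv")
      write_tsv(empty, config$out_dir, "go_homogeneity.tsv")
    }

    stage <- "motifs"
    motif_rows <- list()
    for (gr in groups) {
      prot <- unique(unlist(catalog$members[gr$members], use.names = FALSE))
      sub <- igraph::induced_subgraph(graph, prot)
      cen <- motif_census(sub)
      if (is.null(cen)) next
      sig <- motif_significance(sub, cen, n_random = config$n_random,
                                seed = config$seed, alpha = config$alpha)
      cen2 <- sig$census
      cen2$group_id <- gr$group_id
      motif_rows[[length(motif_rows) + 1L]] <- cen2
    }
    motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
      data.frame(class_id = character(0), size = integer(0),
                 n_edges = integer(0), count = integer(0),
                 null_mean = numeric(0), null_sd = numeric(0),
                 z = numeric(0), p_emp = numeric(0),
                 significant = logical(0), group_id = character(0))
    res$motifs <- motifs
    write_tsv(motifs, config$out_dir, "motifs.tsv")
    message("motifs: ", sum(motifs$count), " motifs, ",
            sum(motifs$count[motifs$significant]), " in significant classes")

    stage <- "modularity"
    modl <- modularity_eval(groups, catalog, graph,
                            algorithm = config$community_algorithm,
                            match_threshold = config$match_threshold,
                            seed = config$seed)
    res$modularity <- modl
    write_tsv(modl, config$out_dir, "modularity.tsv")

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("complexnest")),
      seed = config$seed,
      config = config[setdiff(names(config), "spec")],
      synthetic = !is.null(config$spec),
      spec = if (!is.null(config$spec)) unclass(config$spec) else NULL,
      n_complexes = length(catalog),
      n_groups = length(groups))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }, error = on_fail)
  invisible(res)
}
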