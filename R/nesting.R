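#' Nested pairs of a catalog
#'
#' A nested pair is an ordered pair of complexes in which the smaller
#' member set is a subset of the larger one (meet-min index = 1). Pairs are
#' oriented by placing the complex with more subunits first (the "maximal"
#' side); equal member sets must have been merged beforehand
#' ([dedupe_catalog()]), otherwise orientation is undefined and an error is
#' raised. The subset test is performed on integer counts
#' (intersection == min size), never on floating-point meet-min values.
#'
#' @param matrix a `similarity_matrix` from [all_pairs()].
#' @param catalog the `complex_catalog` the matrix was computed from.
#' @return data.frame with columns `maximal_id`, `sub_id`, `jaccard`.
#' @export
find_nested_pairs <- function(matrix, catalog) {
  sizes <- complex_sizes(catalog)
  sub <- matrix[matrix$subset, , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(maximal_id = character(0), sub_id = character(0),
                      jaccard = numeric(0), stringsAsFactors = FALSE))
  sa <- sizes[sub$id_a]; sb <- sizes[sub$id_b]
  eq <- sa == sb
  if (any(eq))
    stop("equal member sets found (e.g. ", sub$id_a[eq][1], " and ",
         sub$id_b[eq][1], "); run dedupe_catalog() first")
  maximal <- ifelse(sa >= sb, sub$id_a, sub$id_b)
  smaller <- ifelse(sa >= sb, sub$id_b, sub$id_a)
  out <- data.frame(maximal_id = maximal, sub_id = smaller,
                    jaccard = sub$jaccard, stringsAsFactors = FALSE)
  out <- out[order(out$maximal_id, out$sub_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate nested groups
#'
#' The central operation: a nested group is a maximal complex (a complex
#' that is no other complex's strict subset) together with every complex
#' reachable from it in the subset DAG — i.e. all its subcomplexes,
#' sub-subcomplexes and overlapping subcomplexes. The directed graph is
#' built from the oriented nested pairs (edges maximal -> sub); roots are
#' the nodes with no incoming edge; one group is emitted per root that can
#' reach at least one other complex, via depth-first search. After the DFS,
#' each member is re-verified to be a strict subset of the root (for sets
#' this is implied by transitivity, but it is asserted as the redundancy
#' guard), and groups with identical member sets are dropped. A subcomplex
#' shared between two maximal complexes appears in both groups.
#'
#' @param pairs data.frame from [find_nested_pairs()].
#' @param catalog the deduplicated `complex_catalog`.
#' @param merge_overlapping if TRUE, groups sharing at least one subcomplex
#'   are merged into one multi-root group (off by default; the default
#'   one-group-per-root reading is what makes overlapping nesting visible).
#' @return an object of class `nested_groups`: a list of groups, each a
#'   list with `group_id`, `root` (character; >1 only when merged),
#'   `members` (complex ids, root(s) first), `size`, and `edges`
#'   (data.frame `from`, `to` of the induced subset-DAG slice).
#' @export
nested_groups <- function(pairs, catalog, merge_overlapping = FALSE) {
  stopifnot(is.data.frame(pairs))
  out <- list()
  if (nrow(pairs)) {
    nodes <- unique(c(pairs$maximal_id, pairs$sub_id))
    g <- igraph::graph_from_data_frame(
      pairs[c("maximal_id", "sub_id")], directed = TRUE,
      vertices = data.frame(name = nodes))
    if (!igraph::is_dag(g))
      stop("subset graph contains a cycle; equal member sets escaped dedupe")
    roots <- nodes[igraph::degree(g, v = nodes, mode = "in") == 0L]
    memb <- catalog$members
    groups <- lapply(roots, function(r) {
      reach <- igraph::subcomponent(g, r, mode = "out")
      ids <- igraph::V(g)$name[as.integer(reach)]
      subs <- setdiff(ids, r)
      # redundancy guard: every member must be a strict subset of the root
      ok <- vapply(subs, function(s) all(memb[[s]] %in% memb[[r]]) &&
                     length(memb[[s]]) < length(memb[[r]]), TRUE)
      if (!all(ok))
        stop("group member not a subset of root ", r, ": ",
             paste(subs[!ok], collapse = ", "))
      ids <- c(r, sort(subs))
      sl <- pairs$maximal_id %in% ids & pairs$sub_id %in% ids
      list(root = r, members = ids, size = length(ids),
           edges = data.frame(from = pairs$maximal_id[sl],
                              to = pairs$sub_id[sl],
                              stringsAsFactors = FALSE))
    })
    # drop duplicate groups (identical member_id sets)
    key <- vapply(groups, function(gr) paste(sort(gr$members), collapse = "\r"), "")
    groups <- groups[!duplicated(key)]
    if (merge_overlapping && length(groups) > 1L) {
      repeat {
        merged <- FALSE
        for (i in seq_along(groups)) {
          for (j in seq_along(groups)) {
            if (j <= i) next
            shared <- intersect(setdiff(groups[[i]]$members, groups[[i]]$root),
                                setdiff(groups[[j]]$members, groups[[j]]$root))
            if (length(shared)) {
              a <- groups[[i]]; b <- groups[[j]]
              ids <- unique(c(a$root, b$root,
                              sort(setdiff(c(a$members, b$members),
                                           c(a$root, b$root)))))
              sl <- pairs$maximal_id %in% ids & pairs$sub_id %in% ids
              groups[[i]] <- list(root = unique(c(a$root, b$root)),
                                  members = ids, size = length(ids),
                                  edges = data.frame(
                                    from = pairs$maximal_id[sl],
                                    to = pairs$sub_id[sl],
                                    stringsAsFactors = FALSE))
              groups[[j]] <- NULL
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
        if (!merged) break
      }
    }
    out <- groups
  }
  out <- out[order(vapply(out, function(gr) gr$root[1], ""))]
  for (k in seq_along(out)) out[[k]]$group_id <- sprintf("NG_%04d", k)
  structure(out, class = "nested_groups", catalog_n = length(catalog))
}

#' @export
print.nested_groups <- function(x, ...) {
  cat("nested_groups: ", length(x), " group(s)\n", sep = "")
  if (length(x)) {
    sz <- vapply(x, function(g) g$size, 1L)
    cat("  sizes (complexes per group): min ", min(sz), ", median ",
        stats::median(sz), ", max ", max(sz), "\n", sep = "")
    cat("  groups with >= 3 subcomplexes: ", sum(sz - 1L >= 3L), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.nested_groups <- function(object, ...) {
  df <- data.frame(
    group_id = vapply(object, function(g) g$group_id, ""),
    root = vapply(object, function(g) paste(g$root, collapse = "|"), ""),
    n_complexes = vapply(object, function(g) g$size, 1L),
    n_subcomplexes = vapply(object, function(g) g$size - length(g$root), 1L),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Filter a reliable set of nested groups
#'
#' High Jaccard between a maximal complex and its single subcomplex (the
#' two sets differing by one or a few subunits) is the signature of a
#' duplicated record with dropped subunits — an integration artifact rather
#' than biology. The default therefore removes size-2 groups whose pair
#' Jaccard exceeds the threshold. Larger groups are never removed, only
#' flagged per offending pair. The opposite direction (`exclude_below`) is
#' available for analyses that instead want only the near-duplicates.
#'
#' @param groups a `nested_groups` object.
#' @param pairs the nested pairs the groups were built from.
#' @param jaccard_threshold numeric in `[0, 1]`; default 0.85.
#' @param direction `"exclude_above"` (default) or `"exclude_below"`.
#' @return a `nested_groups` object; kept groups gain a `flagged_pairs`
#'   data.frame of offending pairs (possibly empty).
#' @export
filter_reliable <- function(groups, pairs, jaccard_threshold = 0.85,
                            direction = c("exclude_above", "exclude_below")) {
  direction <- match.arg(direction)
  stopifnot(jaccard_threshold >= 0, jaccard_threshold <= 1)
  offending <- if (direction == "exclude_above")
    pairs$jaccard > jaccard_threshold else pairs$jaccard < jaccard_threshold
  bad_key <- paste(pairs$maximal_id, pairs$sub_id)[offending]
  keep <- logical(length(groups))
  out <- list()
  for (k in seq_along(groups)) {
    gr <- groups[[k]]
    sl <- paste(gr$edges$from, gr$edges$to) %in% bad_key
    if (gr$size == 2L && any(sl)) next
    gr$flagged_pairs <- gr$edges[sl, , drop = FALSE]
    out[[length(out) + 1L]] <- gr
  }
  structure(out, class = "nested_groups",
            catalog_n = attr(groups, "catalog_n"))
}

#' Shared / nonshared partition of a nested group
#'
#' Within a group, a shared protein is one present in at least two member
#' complexes; since every subcomplex protein also belongs to the root,
#' shared = union of all subcomplex member sets. Nonshared proteins belong
#' to the maximal complex only. The two classes partition the root's
#' member set.
#'
#' @param group one element of a `nested_groups` object.
#' @param catalog the `complex_catalog`.
#' @return list with character vectors `shared` and `nonshared`.
#' @export
shared_partition <- function(group, catalog) {
  root_members <- sort(unique(unlist(catalog$members[group$root],
                                     use.names = FALSE)))
  subs <- setdiff(group$members, group$root)
  shared <- sort(unique(unlist(catalog$members[subs], use.names = FALSE)))
  list(shared = shared, nonshared = setdiff(root_members, shared))
}

#' Pooled shared / nonshared classification
#'
#' Pools [shared_partition()] over all groups. Counting is per group
#' instance: a protein shared in one group and nonshared in another
#' contributes to both tallies (`instances`), which is the consistent
#' reading when groups overlap. For per-protein downstream use (metric
#' comparisons) each protein also receives a single class: `shared` if
#' shared in any group, else `nonshared` if nonshared in any group, else
#' `neither`.
#'
#' @param groups a `nested_groups` object.
#' @param catalog the `complex_catalog`.
#' @return list with `class` (named character vector over the catalog's
#'   protein universe) and `instances` (data.frame `group_id`, `protein`,
#'   `class`, one row per group instance).
#' @export
classify_proteins <- function(groups, catalog) {
  rows <- lapply(groups, function(gr) {
    p <- shared_partition(gr, catalog)
    data.frame(group_id = gr$group_id,
               protein = c(p$shared, p$nonshared),
               class = rep(c("shared", "nonshared"),
                           c(length(p$shared), length(p$nonshared))),
               stringsAsFactors = FALSE)
  })
  inst <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_id = character(0), protein = character(0),
               class = character(0), stringsAsFactors = FALSE)
  univ <- protein_universe(catalog)
  cls <- stats::setNames(rep("neither", length(univ)), univ)
  cls[unique(inst$protein[inst$class == "nonshared"])] <- "nonshared"
  cls[unique(inst$protein[inst$class == "shared"])] <- "shared"
  list(class = cls, instances = inst)
}

#' Provenance analysis of nested groups
#'
#' Flags, per group, whether every member complex shares one identical
#' (pub_id, source_db) provenance pair (`same_source`) — evidence that the
#' authors knew of both the complex and its subcomplexes, i.e. the nesting
#' is curated rather than an integration accident. For size-2 groups it
#' additionally tabulates, per Jaccard bin, the total number of cases and
#' the number coming from more than one paper or database
#' (`multisource_count`): artifacts concentrate in the high-Jaccard bins
#' and are always multi-source.
#'
#' @param groups a `nested_groups` object.
#' @param catalog the `complex_catalog`.
#' @param bins number of equal Jaccard bins on (0, 1] for the size-2 table.
#' @return list with `per_group` (data.frame `group_id`, `same_source`,
#'   `provenance_known`) and `size2` (data.frame `bin_lo`, `bin_hi`,
#'   `total_count`, `multisource_count`).
#' @export
provenance_analysis <- function(groups, catalog, bins = 20L) {
  prov_pairs <- function(id) {
    p <- catalog$pub_id[[id]]; s <- catalog$source_db[[id]]
    keep <- !(is.na(p) & is.na(s))
    if (!any(keep)) return(character(0))
    paste(p[keep], s[keep], sep = "\r")
  }
  per_group <- data.frame(group_id = character(0), same_source = logical(0),
                          provenance_known = logical(0))
  j2 <- numeric(0); multi2 <- logical(0)
  for (gr in groups) {
    pp <- lapply(gr$members, prov_pairs)
    known <- all(vapply(pp, length, 1L) > 0L)
    same <- known && length(Reduce(intersect, pp)) > 0L
    per_group <- rbind(per_group, data.frame(
      group_id = gr$group_id, same_source = if (known) same else NA,
      provenance_known = known, stringsAsFactors = FALSE))
    if (gr$size == 2L && known) {
      a <- catalog$members[[gr$members[1]]]
      b <- catalog$members[[gr$members[2]]]
      i <- length(intersect(a, b))
      j2 <- c(j2, i / (length(a) + length(b) - i))
      # multi-source: the union of provenance pairs over the two complexes
      # spans more than one distinct (paper, database) pair
      multi2 <- c(multi2, length(unique(unlist(pp))) > 1L)
    }
  }
  edges <- seq(0, 1, length.out = bins + 1L)
  bin <- cut(j2, breaks = edges, right = TRUE, include.lowest = FALSE)
  size2 <- data.frame(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
    total_count = as.integer(table(bin)),
    multisource_count = as.integer(
      if (length(j2)) tapply(multi2, bin, sum, default = 0L)
      else rep(0L, bins)))
  list(per_group = per_group, size2 = size2)
}

#' Export nested groups as JSON
#' @param groups a `nested_groups` object.
#' @param catalog the `complex_catalog` (member sets are embedded).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_groups_json <- function(groups, catalog, path) {
  obj <- lapply(groups, function(gr) {
    list(group_id = gr$group_id, root = gr$root, members = gr$members,
         size = gr$size,
         dag_edges = gr$edges,
         proteins = lapply(catalog$members[gr$members], identity))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export nested groups as flat TSV
#' @param groups a `nested_groups` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(groups, path) {
  df <- summary.nested_groups(groups)
  df$members <- vapply(groups, function(g) paste(g$members, collapse = "|"), "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
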