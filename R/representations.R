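#' Spoke expansion of one complex
#'
#' A copurified group recorded as a spoke model becomes a star: one hub
#' protein linked to every other member. The canonical hub is the
#' experimental bait; when the record carries no bait the fallback is
#' policy-dependent: `"bait"` falls back to the lexicographically smallest
#' member (deterministic), `"lexicographic"` always uses the smallest
#' member, `"seeded_random"` draws the hub from the members using the
#' supplied seed (emulating analysts that pick a random protein of the
#' group).
#'
#' @param members character vector of member proteins (>= 1).
#' @param complex_id label attached to every produced edge.
#' @param bait optional bait protein (`NA` = absent).
#' @param hub_policy `"bait"`, `"lexicographic"` or `"seeded_random"`.
#' @param seed integer seed for `"seeded_random"`.
#' @return data.frame `from`, `to`, `complex_id` with |members| - 1 rows,
#'   all incident to the hub; zero rows for singletons.
#' @export
expand_spoke <- function(members, complex_id, bait = NA_character_,
                         hub_policy = c("bait", "lexicographic",
                                        "seeded_random"),
                         seed = NULL) {
  hub_policy <- match.arg(hub_policy)
  members <- sort(unique(as.character(members)))
  if (length(members) < 2L)
    return(data.frame(from = character(0), to = character(0),
                      complex_id = character(0), stringsAsFactors = FALSE))
  hub <- switch(hub_policy,
    bait = if (!is.na(bait)) bait else members[1],
    lexicographic = members[1],
    seeded_random = {
      if (is.null(seed)) stop("seeded_random hub policy requires a seed")
      # per-record offset keeps hub choice independent across records
      set.seed((seed + sum(utf8ToInt(paste(complex_id, collapse = "")))) %% .Machine$integer.max)
      sample(members, 1L)
    })
  if (!hub %in% members)
    stop("bait ", hub, " is not a member of complex ", complex_id)
  others <- setdiff(members, hub)
  data.frame(from = rep(hub, length(others)), to = others,
             complex_id = rep(as.character(complex_id), length(others)),
             stringsAsFactors = FALSE)
}

#' Matrix expansion of one complex
#'
#' All pairwise interactions between members are assumed: the complete
#' graph on the member set, C(|members|, 2) edges, each labeled with the
#' complex identifier.
#'
#' @inheritParams expand_spoke
#' @return data.frame `from`, `to`, `complex_id`.
#' @export
expand_matrix <- function(members, complex_id) {
  members <- sort(unique(as.character(members)))
  if (length(members) < 2L)
    return(data.frame(from = character(0), to = character(0),
                      complex_id = character(0), stringsAsFactors = FALSE))
  p <- utils::combn(members, 2L)
  data.frame(from = p[1L, ], to = p[2L, ],
             complex_id = rep(as.character(complex_id), ncol(p)),
             stringsAsFactors = FALSE)
}

catalog_edges <- function(catalog, model = c("spoke", "matrix"),
                          hub_policy = "bait", seed = NULL) {
  model <- match.arg(model)
  singletons <- complex_sizes(catalog) < 2L
  if (any(singletons))
    message(sum(singletons), " singleton complex(es) yield no edges")
  rows <- lapply(seq_along(catalog$complex_id), function(i) {
    if (model == "spoke")
      expand_spoke(catalog$members[[i]], catalog$complex_id[i],
                   catalog$bait[i], hub_policy, seed)
    else
      expand_matrix(catalog$members[[i]], catalog$complex_id[i])
  })
  ed <- do.call(rbind, rows)
  if (is.null(ed))
    ed <- data.frame(from = character(0), to = character(0),
                     complex_id = character(0), stringsAsFactors = FALSE)
  ed
}

#' Build a protein-level interaction graph in one of four views
#'
#' Expands every complex in the catalog under the chosen model and
#' assembles the protein-level graph in one of the four multi-membership
#' views:
#' \describe{
#'   \item{multiedge}{one node per protein; parallel edges allowed, one
#'     edge per (protein pair, complex). The working view for all network
#'     metrics: multiple edges mean membership to multiple complexes.}
#'   \item{multihub}{hub nodes are split into one composite node
#'     (`protein@complex`) per complex; non-hub proteins stay single
#'     nodes. Single edges, one clear star per complex, but the node count
#'     is artificially inflated. Spoke model only.}
#'   \item{multinode}{every node is split per complex; the graph is a
#'     disjoint union of one component per (multi-member) complex.}
#'   \item{node_attribute}{a simple graph (at most one edge per pair); the
#'     complex membership moves into a node attribute `complexes`
#'     (pipe-separated complex ids) — the pie-chart view.}
#' }
#'
#' @param catalog a `complex_catalog`.
#' @param model `"spoke"` or `"matrix"`.
#' @param view_mode one of `"multiedge"`, `"multihub"`, `"multinode"`,
#'   `"node_attribute"`.
#' @param hub_policy,seed passed to [expand_spoke()].
#' @return an igraph object; edges carry a `complex_id` attribute (except
#'   in the node_attribute view), nodes carry `protein` and, in split
#'   views, `complex`. Graph attributes `view_mode` and `model` record the
#'   construction.
#' @export
build_view <- function(catalog, model = c("spoke", "matrix"),
                       view_mode = c("multiedge", "multihub", "multinode",
                                     "node_attribute"),
                       hub_policy = "bait", seed = NULL) {
  model <- match.arg(model)
  view_mode <- match.arg(view_mode)
  if (view_mode == "multihub" && model == "matrix")
    stop("multihub view requires a spoke model: a matrix expansion has no hub")
  ed <- catalog_edges(catalog, model, hub_policy, seed)
  nodes_all <- protein_universe(catalog)
  g <- switch(view_mode,
    multiedge = {
      g <- igraph::graph_from_data_frame(
        ed, directed = FALSE, vertices = data.frame(name = nodes_all))
      igraph::V(g)$protein <- igraph::V(g)$name
      g
    },
    multihub = {
      hubs <- unique(ed$from)
      e2 <- ed
      e2$from <- paste0(e2$from, "@", e2$complex_id)
      verts <- unique(data.frame(
        name = c(e2$from, setdiff(nodes_all, hubs)),
        stringsAsFactors = FALSE))
      g <- igraph::graph_from_data_frame(e2, directed = FALSE,
                                         vertices = verts)
      igraph::V(g)$protein <- sub("@.*$", "", igraph::V(g)$name)
      igraph::V(g)$complex <- ifelse(grepl("@", igraph::V(g)$name),
                                     sub("^.*@", "", igraph::V(g)$name),
                                     NA_character_)
      g
    },
    multinode = {
      e2 <- ed
      e2$from <- paste0(e2$from, "@", e2$complex_id)
      e2$to <- paste0(e2$to, "@", e2$complex_id)
      g <- igraph::graph_from_data_frame(
        e2, directed = FALSE,
        vertices = data.frame(name = unique(c(e2$from, e2$to))))
      igraph::V(g)$protein <- sub("@.*$", "", igraph::V(g)$name)
      igraph::V(g)$complex <- sub("^.*@", "", igraph::V(g)$name)
      g
    },
    node_attribute = {
      key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), sep = "\r")
      e2 <- ed[!duplicated(key), c("from", "to"), drop = FALSE]
      g <- igraph::graph_from_data_frame(
        e2, directed = FALSE, vertices = data.frame(name = nodes_all))
      memb_of <- lapply(stats::setNames(nodes_all, nodes_all),
                        function(p) catalog$complex_id[
                          vapply(catalog$members, function(m) p %in% m, TRUE)])
      igraph::V(g)$protein <- igraph::V(g)$name
      igraph::V(g)$complexes <- vapply(memb_of[igraph::V(g)$name],
                                       paste, "", collapse = "|")
      g
    })
  g <- igraph::set_graph_attr(g, "view_mode", view_mode)
  igraph::set_graph_attr(g, "model", model)
}

#' Export an interaction graph to GraphML
#'
#' Writes the graph with its `complex_id` edge attribute (and `complexes`
#' node attribute in the node_attribute view); re-importing with
#' [import_graphml()] preserves the node set and the labeled-edge multiset.
#'
#' @param graph an igraph object from [build_view()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Import a GraphML interaction graph
#' @param path GraphML file path.
#' @return an igraph object.
#' @export
import_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Simple projection of a multiedge graph
#'
#' Collapses parallel edges; each surviving edge carries a `multiplicity`
#' attribute (number of complexes generating that protein pair).
#'
#' @param graph a multiedge igraph from [build_view()].
#' @return a simple igraph with edge attribute `multiplicity`.
#' @export
simple_projection <- function(graph) {
  igraph::E(graph)$multiplicity <- 1
  igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(multiplicity = "sum",
                                         complex_id = "ignore"))
}
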