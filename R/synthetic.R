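#' Specification for the synthetic catalog generator
#'
#' Bundles every knob of the generator with defaults that emulate the
#' published global statistics of a consolidated human complex catalog:
#' complex sizes follow a discretized log-normal (mode 3, mean about 7.24,
#' truncated to `[size_min, size_cap]`); a fraction of maximal complexes
#' carries planted subcomplexes (multi-level, optionally overlapping);
#' duplicated-with-dropped-subunit artifact records and non-nested noise
#' complexes emulate database integration errors; provenance pairs and
#' GO-like annotations with tunable coherence complete the picture. All
#' randomness flows from `seed`.
#'
#' @param seed integer seed driving every random draw.
#' @param n_proteins size of the protein universe.
#' @param n_maximal number of maximal complexes drawn.
#' @param size_meanlog,size_sdlog,size_min,size_cap size distribution:
#'   rounded log-normal truncated to `[size_min, size_cap]`.
#' @param p_nested probability a complex (maximal, or subcomplex during
#'   recursion) receives planted subcomplexes.
#' @param n_sub_lambda subcomplex count per nested complex is
#'   `1 + rpois(n_sub_lambda)`.
#' @param sub_size_lambda subcomplex size is `2 + rpois(sub_size_lambda)`,
#'   capped at parent size - 1 (small sizes dominate).
#' @param depth_max maximum nesting depth (1 = no sub-subcomplexes).
#' @param p_overlap_sub probability a later sibling subcomplex is forced
#'   to share members with an earlier one.
#' @param p_shared_root probability a nested maximal complex gets a second
#'   maximal complex planted over its subcomplexes (two roots sharing
#'   subcomplexes — the overlapping-nesting topology).
#' @param n_noise number of noise complexes that overlap existing ones
#'   without any subset relation (meet-min < 1 against everything).
#' @param artifact_rate probability a maximal complex is duplicated into a
#'   second source with `artifact_drop` members dropped.
#' @param artifact_drop members dropped per artifact record (default 1).
#' @param sources list of `c(pub_id, source_db)` provenance pairs.
#' @param p_same_source probability a planted group inherits its root's
#'   provenance pair wholesale (curated-looking group).
#' @param vocab named vector: term vocabulary size per ontology.
#' @param seed_terms_lambda per-complex seed term set size is
#'   `1 + rpois(seed_terms_lambda)` per ontology.
#' @param coherence probability a member inherits each seed term of its
#'   complex.
#' @param background_lambda per-protein background term count
#'   (`rpois(background_lambda)` per ontology).
#' @param shared_surplus named vector: extra random terms per ontology
#'   given to each planted-shared protein (drives the term-count excess of
#'   the shared class for BP/CC).
#' @param essential_base,essential_boost essentiality probability is
#'   `essential_base` plus `essential_boost` for planted-shared proteins.
#' @param disease_rate uniform disease-flag probability (no class effect:
#'   the planted negative control).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_proteins = 300L,
                           n_maximal = 150L,
                           size_meanlog = 1.40, size_sdlog = 0.83,
                           size_min = 3L, size_cap = 50L,
                           p_nested = 0.3,
                           n_sub_lambda = 1,
                           sub_size_lambda = 1.5,
                           depth_max = 2L,
                           p_overlap_sub = 0.3,
                           p_shared_root = 0.05,
                           n_noise = 15L,
                           artifact_rate = 0.1,
                           artifact_drop = 1L,
                           sources = list(c("pm1", "dbA"), c("pm2", "dbA"),
                                          c("pm3", "dbB"), c("pm4", "dbB"),
                                          c("pm5", "dbC"), c("pm6", "dbC")),
                           p_same_source = 0.15,
                           vocab = c(BP = 300L, MF = 150L, CC = 100L),
                           seed_terms_lambda = 2,
                           coherence = 0.7,
                           background_lambda = 2,
                           shared_surplus = c(BP = 2L, MF = 0L, CC = 2L),
                           essential_base = 0.15,
                           essential_boost = 0.35,
                           disease_rate = 0.1) {
  probs <- c(p_nested, p_overlap_sub, p_shared_root, artifact_rate,
             p_same_source, coherence, essential_base, disease_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (essential_base + essential_boost > 1)
    stop("essential_base + essential_boost must not exceed 1")
  if (depth_max < 1L) stop("depth_max must be >= 1")
  if (size_min < 2L) stop("size_min must be >= 2")
  spec <- as.list(environment())
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec: ", x$n_maximal, " maximal complexes over ",
      x$n_proteins, " proteins (seed ", x$seed, ")\n",
      "  p_nested ", x$p_nested, ", depth_max ", x$depth_max,
      ", artifact_rate ", x$artifact_rate, ", n_noise ", x$n_noise,
      "\n", sep = "")
  invisible(x)
}

draw_size <- function(spec) {
  repeat {
    s <- round(stats::rlnorm(1, spec$size_meanlog, spec$size_sdlog))
    if (s >= spec$size_min && s <= spec$size_cap) return(as.integer(s))
  }
}

# TRUE when cand has a subset/superset/equality relation with any set in
# `sets` whose id is not in `allowed`
set_conflict <- function(cand, sets, allowed = character(0)) {
  for (id in names(sets)) {
    if (id %in% allowed) next
    s <- sets[[id]]
    if (all(cand %in% s) || all(s %in% cand)) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic complex catalog with known structure
#'
#' Emits a catalog, an annotation table and the planted ground truth. The
#' generator guarantees that in an artifact-free, noise-free run the only
#' subset relations present are the planted ones (candidate sets that
#' would accidentally nest with a complex outside their own lineage are
#' resampled), so nested-group detection must recover the ground truth
#' exactly. Artifact records are strict subsets of their original with
#' `artifact_drop` members removed and a different provenance pair:
#' Jaccard (s - drop) / s, always multi-source — the planted
#' integration-error signal. Identical `spec` (including its seed) gives a
#' byte-identical result.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `catalog` (`complex_catalog`), `annotations`
#'   (`annotation_table`) and `truth` (class `synthetic_truth`): planted
#'   `groups` (list of `root`, `members`), `artifact_pairs` (data.frame),
#'   `class` (named planted shared/nonshared/neither vector) and the spec.
#' @export
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  universe <- sprintf("P%04d", seq_len(spec$n_proteins))
  sets <- list()          # id -> member set, all emitted records
  lineage <- list()       # id -> ids of planted ancestors/descendants
  children <- list()      # id -> direct planted subcomplex ids
  roots <- character(0)

  add_subcomplexes <- function(parent_id, depth) {
    # recursive planting; returns nothing, mutates sets/children via <<-
    pm <- sets[[parent_id]]
    n_sub <- 1L + stats::rpois(1, spec$n_sub_lambda)
    sibs <- character(0)
    for (si in seq_len(n_sub)) {
      placed_id <- NULL
      for (try in 1:50) {
        k <- min(length(pm) - 1L, 2L + stats::rpois(1, spec$sub_size_lambda))
        if (k < 2L) break
        cand <- if (length(sibs) && stats::runif(1) < spec$p_overlap_sub) {
          ov <- sets[[sample(sibs, 1)]]
          core <- sample(intersect(ov, pm), min(k - 1L, length(ov)))
          extra <- setdiff(pm, core)
          sort(unique(c(core, sample(extra, min(k - length(core),
                                                length(extra))))))
        } else sort(sample(pm, k))
        if (length(cand) < 2L) next
        allowed <- c(parent_id, ancestors(parent_id))
        if (!set_conflict(cand, sets, allowed)) {
          id <- sprintf("%s.s%d", parent_id, si)
          sets[[id]] <<- cand
          children[[parent_id]] <<- c(children[[parent_id]], id)
          placed_id <- id
          if (depth < spec$depth_max && length(cand) >= 3L &&
              stats::runif(1) < spec$p_nested)
            add_subcomplexes(id, depth + 1L)
          break
        }
      }
      if (!is.null(placed_id)) sibs <- c(sibs, placed_id)
    }
  }
  ancestors <- function(id) {
    out <- character(0)
    repeat {
      parent <- sub("\\.s[0-9]+$", "", id)
      if (parent == id) break
      out <- c(out, parent); id <- parent
    }
    out
  }
  descendants <- function(id) {
    kids <- children[[id]]
    if (is.null(kids)) return(character(0))
    c(kids, unlist(lapply(kids, descendants), use.names = FALSE))
  }

  # --- maximal complexes -------------------------------------------------
  for (i in seq_len(spec$n_maximal)) {
    for (try in 1:200) {
      s <- draw_size(spec)
      cand <- sort(sample(universe, s))
      if (!set_conflict(cand, sets)) {
        id <- sprintf("cx%04d", i)
        sets[[id]] <- cand
        roots <- c(roots, id)
        if (s >= 3L && stats::runif(1) < spec$p_nested)
          add_subcomplexes(id, 1L)
        break
      }
    }
  }

  # --- second roots over existing subcomplexes (overlapping nesting) -----
  extra_roots <- character(0)
  for (r in roots) {
    subs <- descendants(r)
    if (!length(subs) || stats::runif(1) >= spec$p_shared_root) next
    for (try in 1:50) {
      base <- sort(unique(unlist(sets[subs], use.names = FALSE)))
      pool <- setdiff(universe, sets[[r]])
      n_extra <- max(1L, 1L + stats::rpois(1, 2))
      if (length(pool) < n_extra) break
      cand <- sort(unique(c(base, sample(pool, n_extra))))
      # the new root must contain the subs but neither contain nor be
      # contained in any other record (in particular not in r itself)
      if (!set_conflict(cand, sets, allowed = subs)) {
        id <- sprintf("%s.alt", r)
        sets[[id]] <- cand
        children[[id]] <- subs
        extra_roots <- c(extra_roots, id)
        break
      }
    }
  }
  roots <- c(roots, extra_roots)

  # --- ground-truth groups ----------------------------------------------
  gt_groups <- list()
  for (r in roots) {
    subs <- unique(descendants(r))
    if (length(subs))
      gt_groups[[length(gt_groups) + 1L]] <-
        list(root = r, members = c(r, sort(subs)))
  }

  # --- artifact duplicates ----------------------------------------------
  artifact_pairs <- data.frame(maximal_id = character(0),
                               artifact_id = character(0),
                               jaccard = numeric(0), stringsAsFactors = FALSE)
  base_ids <- names(sets)
  for (id in base_ids) {
    if (!grepl("^cx[0-9]+$", id)) next
    if (stats::runif(1) >= spec$artifact_rate) next
    m <- sets[[id]]
    if (length(m) <= spec$artifact_drop + 1L) next
    for (try in 1:20) {
      cand <- sort(sample(m, length(m) - spec$artifact_drop))
      equal_any <- any(vapply(sets, function(s)
        length(s) == length(cand) && all(s %in% cand), TRUE))
      if (!equal_any &&
          !set_conflict(cand, sets, allowed = c(id, ancestors(id),
                                                descendants(id)))) {
        aid <- paste0(id, ".art")
        sets[[aid]] <- cand
        artifact_pairs <- rbind(artifact_pairs, data.frame(
          maximal_id = id, artifact_id = aid,
          jaccard = length(cand) / length(m), stringsAsFactors = FALSE))
        break
      }
    }
  }

  # --- noise complexes (overlap without nesting) -------------------------
  n_noise_placed <- 0L
  if (spec$n_noise > 0L && length(sets)) {
    for (i in seq_len(spec$n_noise)) {
      for (try in 1:100) {
        tmpl <- sets[[sample(length(sets), 1)]]
        j <- sample(max(1L, length(tmpl) - 1L), 1)
        outside <- setdiff(universe, tmpl)
        n_out <- max(1L, 1L + stats::rpois(1, 1))
        if (length(outside) < n_out) next
        cand <- sort(unique(c(sample(tmpl, j), sample(outside, n_out))))
        if (length(cand) < 2L) next
        if (!set_conflict(cand, sets)) {
          sets[[sprintf("nz%04d", i)]] <- cand
          n_noise_placed <- n_noise_placed + 1L
          break
        }
      }
    }
  }

  # --- provenance and baits ---------------------------------------------
  ids <- names(sets)
  src_idx <- sample(length(spec$sources), length(ids), replace = TRUE)
  names(src_idx) <- ids
  for (gr in gt_groups) {
    if (stats::runif(1) < spec$p_same_source)
      src_idx[gr$members] <- src_idx[gr$root]
  }
  for (k in seq_len(nrow(artifact_pairs))) {
    orig <- src_idx[artifact_pairs$maximal_id[k]]
    others <- setdiff(seq_along(spec$sources), orig)
    src_idx[artifact_pairs$artifact_id[k]] <- sample(others, 1)
  }
  pub <- vapply(spec$sources[src_idx], `[`, "", 1L)
  db <- vapply(spec$sources[src_idx], `[`, "", 2L)
  bait <- vapply(sets, function(m) sample(m, 1L), "")
  catalog <- complex_catalog(ids, sets, bait, pub, db)

  # --- planted protein classes ------------------------------------------
  cls <- stats::setNames(rep("neither", length(universe)), universe)
  inst_shared <- character(0); inst_nonshared <- character(0)
  for (gr in gt_groups) {
    shared <- sort(unique(unlist(sets[setdiff(gr$members, gr$root)],
                                 use.names = FALSE)))
    nonshared <- setdiff(sets[[gr$root]], shared)
    inst_shared <- c(inst_shared, shared)
    inst_nonshared <- c(inst_nonshared, nonshared)
  }
  cls[unique(inst_nonshared)] <- "nonshared"
  cls[unique(inst_shared)] <- "shared"

  # --- annotations -------------------------------------------------------
  onts <- c("BP", "MF", "CC")
  terms <- lapply(stats::setNames(onts, onts), function(o)
    sprintf("%s%04d", o, seq_len(spec$vocab[[o]])))
  prot_terms <- lapply(stats::setNames(onts, onts), function(o)
    stats::setNames(rep(list(character(0)), length(universe)), universe))
  for (id in ids) {
    m <- sets[[id]]
    for (o in onts) {
      ns <- 1L + stats::rpois(1, spec$seed_terms_lambda)
      seed_set <- sample(terms[[o]], min(ns, length(terms[[o]])))
      for (p in m) {
        inherit <- seed_set[stats::runif(length(seed_set)) < spec$coherence]
        prot_terms[[o]][[p]] <- c(prot_terms[[o]][[p]], inherit)
      }
    }
  }
  for (p in universe) {
    for (o in onts) {
      nb <- stats::rpois(1, spec$background_lambda)
      if (nb > 0L)
        prot_terms[[o]][[p]] <- c(prot_terms[[o]][[p]],
                                  sample(terms[[o]], min(nb, length(terms[[o]]))))
      if (cls[p] == "shared" && spec$shared_surplus[[o]] > 0L)
        prot_terms[[o]][[p]] <- c(prot_terms[[o]][[p]],
                                  sample(terms[[o]], spec$shared_surplus[[o]]))
      prot_terms[[o]][[p]] <- sort(unique(prot_terms[[o]][[p]]))
    }
  }
  p_ess <- spec$essential_base +
    spec$essential_boost * (cls[universe] == "shared")
  essential <- stats::runif(length(universe)) < p_ess
  disease <- stats::runif(length(universe)) < spec$disease_rate
  annotations <- annotation_table(universe, prot_terms$BP, prot_terms$MF,
                                  prot_terms$CC, essential, disease)

  truth <- structure(list(groups = gt_groups,
                          artifact_pairs = artifact_pairs,
                          class = cls,
                          n_noise_placed = n_noise_placed,
                          spec = spec),
                     class = "synthetic_truth")
  list(catalog = catalog, annotations = annotations, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth: ", length(x$groups), " planted nested group(s), ",
      nrow(x$artifact_pairs), " artifact pair(s), ",
      x$n_noise_placed, " noise complex(es)\n", sep = "")
  invisible(x)
}

#' Summary statistics of a catalog's protein network
#'
#' The checks used to calibrate the generator against published global
#' catalog statistics: node and edge counts of the expanded graph, the
#' connected-component census (giant component fraction), the complex size
#' histogram and the mean complex size.
#'
#' @param catalog a `complex_catalog`.
#' @param model expansion model for the graph (default spoke).
#' @return list with `n_complexes`, `n_proteins`, `mean_size`,
#'   `size_histogram` (data.frame), `n_nodes`, `n_edges`, `n_components`,
#'   `giant_fraction`.
#' @export
catalog_summary <- function(catalog, model = "spoke") {
  sz <- complex_sizes(catalog)
  g <- build_view(catalog, model = model, view_mode = "multiedge")
  comp <- igraph::components(g)
  list(n_complexes = length(catalog),
       n_proteins = length(protein_universe(catalog)),
       mean_size = mean(sz),
       size_histogram = data.frame(size = as.integer(names(table(sz))),
                                   count = as.integer(table(sz))),
       n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       n_components = comp$no,
       giant_fraction = if (comp$no) max(comp$csize) / igraph::vcount(g)
       else NA_real_)
}
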