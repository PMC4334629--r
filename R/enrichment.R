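#' Upper-tail hypergeometric test
#'
#' Exact probability of observing at least `observed` successes when
#' `sample` draws are taken without replacement from a population of
#' `population` items of which `successes` are successes — the
#' overrepresentation test used for essentiality, disease and
#' subcomplex-count comparisons. P(X >= 0) = 1 by convention.
#'
#' @param population population size.
#' @param successes number of successes in the population.
#' @param sample sample size.
#' @param observed observed successes in the sample.
#' @return list with the four counts and `p_value`.
#' @export
hypergeom_upper <- function(population, successes, sample, observed) {
  if (any(c(population, successes, sample, observed) < 0) ||
      successes > population || sample > population ||
      observed > sample || observed > successes)
    stop("inconsistent hypergeometric counts")
  p <- stats::phyper(observed - 1, successes, population - successes,
                     sample, lower.tail = FALSE)
  list(population_size = population, success_population = successes,
       sample_size = sample, sample_successes = observed,
       p_value = min(1, p))
}

#' Class enrichment in a binary annotation flag
#'
#' Tests whether the shared and the nonshared protein class are each
#' overrepresented in a flag (essentiality or disease involvement). The
#' population defaults to the catalog's protein universe (the network),
#' not the genome; pass `population` to override.
#'
#' @param class named class vector from [classify_proteins()].
#' @param annotations an `annotation_table`.
#' @param flag `"essential"` or `"disease"`.
#' @param population character vector of protein IDs forming the
#'   population; defaults to `names(class)`.
#' @return data.frame with one row per class (`shared`, `nonshared`):
#'   counts, `p_value`, `computable`.
#' @export
class_enrichment <- function(class, annotations,
                             flag = c("essential", "disease"),
                             population = NULL) {
  flag <- match.arg(flag)
  if (is.null(population)) population <- names(class)
  flags <- stats::setNames(rep(FALSE, length(population)), population)
  known <- intersect(population, annotations$protein_id)
  flags[known] <- annotations[[flag]][known]
  rows <- lapply(c("shared", "nonshared"), function(cl) {
    prot <- intersect(names(class)[class == cl], population)
    if (!length(prot))
      return(data.frame(class = cl, population_size = length(population),
                        success_population = sum(flags), sample_size = 0L,
                        sample_successes = 0L, p_value = NA_real_,
                        computable = FALSE, stringsAsFactors = FALSE))
    h <- hypergeom_upper(length(population), sum(flags), length(prot),
                         sum(flags[prot]))
    data.frame(class = cl, population_size = h$population_size,
               success_population = h$success_population,
               sample_size = h$sample_size,
               sample_successes = h$sample_successes,
               p_value = h$p_value, computable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare subcomplex richness of a gold-standard group set
#'
#' Counts the nested groups with at least `k` subcomplexes in a
#' gold-standard (curated) group list and in a full (consolidated) group
#' list, and asks whether the gold standard is overrepresented in
#' subcomplex-rich groups: an upper-tail hypergeometric test of the gold
#' subset against the pooled background (population = both lists pooled,
#' successes = pooled groups with >= k subcomplexes, sample = the gold
#' list).
#'
#' @param groups_ref gold-standard `nested_groups` (or its summary
#'   data.frame).
#' @param groups_all full-catalog `nested_groups` (or summary data.frame).
#' @param k minimum number of subcomplexes (default 3).
#' @return list with per-list counts and proportions and the
#'   hypergeometric `p_value`.
#' @export
subcomplex_count_comparison <- function(groups_ref, groups_all, k = 3L) {
  if (k < 1L) stop("k must be >= 1")
  nsub <- function(g) {
    if (inherits(g, "nested_groups")) g <- summary(g)
    g$n_subcomplexes
  }
  a <- nsub(groups_ref); b <- nsub(groups_all)
  if (!length(a) || !length(b)) stop("both group lists must be nonempty")
  ka <- sum(a >= k); kb <- sum(b >= k)
  h <- hypergeom_upper(length(a) + length(b), ka + kb, length(a), ka)
  list(n_ref = length(a), rich_ref = ka, prop_ref = ka / length(a),
       n_all = length(b), rich_all = kb, prop_all = kb / length(b),
       k = k, p_value = h$p_value)
}

go_sets <- function(annotations, proteins, ontology) {
  col <- c(BP = "go_bp", MF = "go_mf", CC = "go_cc")[[ontology]]
  known <- intersect(proteins, annotations$protein_id)
  annotations[[col]][known]
}

#' GO term counts per class with a Monte Carlo baseline
#'
#' Counts the distinct GO-like terms annotated to the shared class, per
#' ontology. Because the nonshared class is much larger, its count is not
#' compared directly: instead the nonshared value is the mean (and sd) of
#' distinct-term counts over `n_mc` uniform random subsamples of nonshared
#' proteins of the same size as the shared class. An alternative counting
#' mode sums per-protein term counts instead of counting distinct terms.
#'
#' @param class named class vector from [classify_proteins()].
#' @param annotations an `annotation_table`.
#' @param n_mc number of Monte Carlo subsamples (default 1000).
#' @param seed integer seed for the subsampling.
#' @param mode `"distinct"` (default) or `"per_protein_sum"`.
#' @return data.frame with one row per ontology: `ontology`,
#'   `shared_count`, `nonshared_mc_mean`, `nonshared_mc_sd`, `n_shared`,
#'   `n_nonshared`, `undersized` (TRUE when the nonshared pool is smaller
#'   than the shared class, in which case the whole pool is used).
#' @export
go_counts <- function(class, annotations, n_mc = 1000L, seed = 1L,
                      mode = c("distinct", "per_protein_sum")) {
  mode <- match.arg(mode)
  shared <- names(class)[class == "shared"]
  nonshared <- names(class)[class == "nonshared"]
  count <- function(sets) {
    if (mode == "distinct") length(unique(unlist(sets, use.names = FALSE)))
    else sum(vapply(sets, length, 1L))
  }
  undersized <- length(nonshared) < length(shared)
  draw_n <- min(length(shared), length(nonshared))
  set.seed(seed)
  rows <- lapply(c("BP", "MF", "CC"), function(ont) {
    shared_count <- count(go_sets(annotations, shared, ont))
    if (length(nonshared) && draw_n > 0L) {
      sims <- vapply(seq_len(n_mc), function(i) {
        pick <- sample(nonshared, draw_n)
        count(go_sets(annotations, pick, ont))
      }, 1)
      mc_mean <- mean(sims); mc_sd <- stats::sd(sims)
    } else {
      mc_mean <- NA_real_; mc_sd <- NA_real_
    }
    data.frame(ontology = ont, shared_count = shared_count,
               nonshared_mc_mean = mc_mean, nonshared_mc_sd = mc_sd,
               n_shared = length(shared), n_nonshared = length(nonshared),
               undersized = undersized, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' GO term homogeneity of a complex
#'
#' Mean pairwise Jaccard index of the term sets of the complex's annotated
#' members, for one ontology. Members without annotation are excluded (an
#' empty-vs-empty Jaccard is 0/0); the result is absent (`NA`) when fewer
#' than two members are annotated.
#'
#' @param members character vector of member proteins.
#' @param annotations an `annotation_table`.
#' @param ontology `"BP"`, `"MF"` or `"CC"`.
#' @return list with `homogeneity` (`NA` if undefined) and `n_annotated`.
#' @export
go_homogeneity <- function(members, annotations, ontology = c("BP", "MF", "CC")) {
  ontology <- match.arg(ontology)
  sets <- go_sets(annotations, unique(members), ontology)
  sets <- sets[vapply(sets, length, 1L) > 0L]
  n <- length(sets)
  if (n < 2L) return(list(homogeneity = NA_real_, n_annotated = n))
  tot <- 0; np <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    tot <- tot + inter / (length(sets[[i]]) + length(sets[[j]]) - inter)
    np <- np + 1L
  }
  list(homogeneity = tot / np, n_annotated = n)
}
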