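#' Pairwise similarity of two complexes
#'
#' Computes the three set statistics used throughout: the intersection size
#' |A n B|, the meet-min index |A n B| / min(|A|, |B|), and the Jaccard
#' index |A n B| / |A u B|. Meet-min equals 1 exactly when one member set
#' contains the other (perfect nesting); Jaccard equals 1 exactly when the
#' sets are equal. Jaccard <= meet-min always.
#'
#' @param a,b character vectors (member sets) or single-record selections
#'   from a catalog's `members` list. Both must be nonempty.
#' @return list with `intersection`, `meet_min`, `jaccard`.
#' @examples
#' pair_score(c("TIM10", "TIM9"), c("TIM10", "TIM12", "TIM22", "TIM54", "TIM9"))
#' @export
pair_score <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!length(a) || !length(b)) stop("member sets must be nonempty")
  i <- length(intersect(a, b))
  list(intersection = i,
       meet_min = i / min(length(a), length(b)),
       jaccard = i / (length(a) + length(b) - i))
}

#' All-pairs similarity matrix of a catalog
#'
#' Builds the sparse overlap/nesting matrix: for every unordered pair of
#' complexes with at least one shared protein, the intersection size,
#' meet-min and Jaccard indices. Pairs with empty intersection are not
#' stored; their number is `n_possible_pairs - nrow(.)`. The computation
#' walks an inverted index protein -> complexes so only co-membered pairs
#' are touched; the result is identical to the quadratic scan over all
#' n(n-1)/2 pairs.
#'
#' @param catalog a `complex_catalog`.
#' @return an object of class `similarity_matrix`: a data.frame with
#'   columns `id_a`, `id_b` (id_a < id_b lexicographically), `intersection`,
#'   `meet_min`, `jaccard`, plus attributes `n_complexes` and
#'   `n_possible_pairs`. `subset` is TRUE where meet_min == 1 (computed on
#'   integer counts, no float comparison).
#' @export
all_pairs <- function(catalog) {
  n <- length(catalog)
  sizes <- complex_sizes(catalog)
  # inverted index: for each protein, the (integer) complexes containing it
  prot <- unlist(catalog$members, use.names = FALSE)
  cplx <- rep.int(seq_len(n), sizes)
  by_prot <- split(cplx, prot)
  keys <- unlist(lapply(by_prot, function(v) {
    if (length(v) < 2L) return(NULL)
    v <- sort.int(v)
    p <- utils::combn(v, 2L)
    (p[1L, ] - 1) * n + p[2L, ]   # i < j encoded as one number
  }), use.names = FALSE)
  if (length(keys)) {
    tab <- table(keys)
    key <- as.numeric(names(tab))
    i <- floor((key - 1) / n) + 1
    j <- key - (i - 1) * n
    inter <- as.integer(tab)
  } else {
    i <- j <- integer(0); inter <- integer(0)
  }
  id_a <- catalog$complex_id[i]; id_b <- catalog$complex_id[j]
  swap <- id_a > id_b
  tmp <- id_a[swap]; id_a[swap] <- id_b[swap]; id_b[swap] <- tmp
  min_sz <- pmin(sizes[i], sizes[j])
  df <- data.frame(id_a = id_a, id_b = id_b, intersection = inter,
                   meet_min = inter / min_sz,
                   jaccard = inter / (sizes[i] + sizes[j] - inter),
                   subset = inter == min_sz,
                   stringsAsFactors = FALSE)
  df <- df[order(df$id_a, df$id_b), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_complexes = n, n_possible_pairs = n * (n - 1) / 2,
            class = c("similarity_matrix", "data.frame"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix: ", attr(x, "n_complexes"), " complexes, ",
      format(attr(x, "n_possible_pairs"), big.mark = ","),
      " possible pairs, ", nrow(x), " overlapping pairs stored\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Histograms of overlap and nesting
#'
#' Tabulates the stored (nonzero-overlap) pairs: intersection sizes by
#' integer and meet-min values in equal-width right-closed bins, so that a
#' meet-min of exactly 1 lands in the top bin. Zero-overlap pairs are not
#' part of either histogram; their count is reported separately.
#'
#' @param matrix a `similarity_matrix`.
#' @param meet_min_bins number of equal bins on (0, 1] for meet-min.
#' @return list with data.frames `intersection` (`value`, `count`) and
#'   `meet_min` (`bin_lo`, `bin_hi`, `count`), and `n_zero_pairs`.
#' @export
similarity_histograms <- function(matrix, meet_min_bins = 20L) {
  n_zero <- attr(matrix, "n_possible_pairs") - nrow(matrix)
  if (nrow(matrix)) {
    it <- table(matrix$intersection)
    inter <- data.frame(value = as.integer(names(it)),
                        count = as.integer(it))
    edges <- seq(0, 1, length.out = meet_min_bins + 1L)
    bin <- cut(matrix$meet_min, breaks = edges, right = TRUE,
               include.lowest = FALSE)
    mm <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                     count = as.integer(table(bin)))
  } else {
    inter <- data.frame(value = integer(0), count = integer(0))
    mm <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                     count = integer(0))
  }
  list(intersection = inter, meet_min = mm, n_zero_pairs = n_zero)
}

#' Write a similarity matrix to TSV
#' @param matrix a `similarity_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(matrix, path) {
  utils::write.table(as.data.frame(matrix)[
    c("id_a", "id_b", "intersection", "meet_min", "jaccard")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
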