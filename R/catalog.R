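#' Construct a protein-complex catalog
#'
#' A `complex_catalog` holds one record per complex: an identifier, the set
#' of member proteins (subunits), an optional bait protein, and provenance
#' (publication and source database, possibly multi-valued after
#' deduplication). Member lists are treated as sets: order is discarded and
#' duplicate IDs collapse. All set algebra downstream (meet-min, Jaccard,
#' nesting) operates on these sets only.
#'
#' @param complex_id character vector of unique complex identifiers.
#' @param members list of character vectors, one per complex; each the
#'   member protein IDs. Protein IDs are opaque strings (accessions, gene
#'   symbols, and consolidated-database IDs are all accepted unvalidated).
#' @param bait optional character vector of bait proteins (`NA` = absent);
#'   a non-`NA` bait must be a member of its complex.
#' @param pub_id,source_db provenance: either character vectors (one value
#'   per complex, `NA` allowed) or lists of character vectors (multi-valued,
#'   aligned elementwise so that `pub_id[[i]][k]` and `source_db[[i]][k]`
#'   form one provenance pair).
#' @return An object of class `complex_catalog`.
#' @export
complex_catalog <- function(complex_id, members, bait = NULL,
                            pub_id = NULL, source_db = NULL) {
  n <- length(complex_id)
  complex_id <- as.character(complex_id)
  if (anyDuplicated(complex_id))
    stop("duplicate complex_id: ",
         paste(unique(complex_id[duplicated(complex_id)]), collapse = ", "))
  if (length(members) != n)
    stop("members must have one entry per complex_id")
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  empty <- vapply(members, length, 1L) == 0L
  if (any(empty))
    stop("empty member set for complex: ",
         paste(complex_id[empty], collapse = ", "))
  if (is.null(bait)) bait <- rep(NA_character_, n)
  bait <- as.character(bait)
  if (length(bait) != n) stop("bait must have one entry per complex")
  bad <- !is.na(bait) & !mapply(function(b, m) b %in% m, bait, members)
  if (any(bad))
    stop("bait not among members for complex: ",
         paste(complex_id[bad], collapse = ", "))
  as_prov <- function(x) {
    if (is.null(x)) return(rep(list(NA_character_), n))
    if (!is.list(x)) x <- as.list(as.character(x))
    if (length(x) != n) stop("provenance fields must have one entry per complex")
    lapply(x, as.character)
  }
  pub_id <- as_prov(pub_id)
  source_db <- as_prov(source_db)
  ok <- mapply(function(p, s) length(p) == length(s), pub_id, source_db)
  if (!all(ok)) stop("pub_id and source_db must be aligned per record")
  names(members) <- names(bait) <- names(pub_id) <- names(source_db) <- complex_id
  structure(list(complex_id = complex_id, members = members, bait = bait,
                 pub_id = pub_id, source_db = source_db),
            class = "complex_catalog")
}

#' Number of complexes in a catalog
#' @param x a `complex_catalog`.
#' @param ... ignored.
#' @export
length.complex_catalog <- function(x) length(x$complex_id)

#' Protein universe of a catalog
#'
#' The union of all member sets.
#' @param catalog a `complex_catalog`.
#' @return sorted character vector of protein IDs.
#' @export
protein_universe <- function(catalog) {
  sort(unique(unlist(catalog$members, use.names = FALSE)))
}

#' Sizes of the member sets
#' @param catalog a `complex_catalog`.
#' @return named integer vector.
#' @export
complex_sizes <- function(catalog) {
  vapply(catalog$members, length, 1L)
}

#' @export
print.complex_catalog <- function(x, ...) {
  sz <- complex_sizes(x)
  cat("complex_catalog: ", length(x), " complexes, ",
      length(protein_universe(x)), " proteins\n", sep = "")
  if (length(x))
    cat("  member-set sizes: min ", min(sz), ", median ", stats::median(sz),
        ", mean ", round(mean(sz), 2), ", max ", max(sz), "\n", sep = "")
  invisible(x)
}

#' Subset a catalog by complex identifier
#' @param catalog a `complex_catalog`.
#' @param ids complex identifiers to keep (order preserved).
#' @return a `complex_catalog` with the selected records.
#' @export
catalog_subset <- function(catalog, ids) {
  idx <- match(ids, catalog$complex_id)
  if (anyNA(idx)) stop("unknown complex_id: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  complex_catalog(catalog$complex_id[idx], catalog$members[idx],
                  catalog$bait[idx], catalog$pub_id[idx],
                  catalog$source_db[idx])
}

split_field <- function(x) {
  x <- as.character(x)
  out <- strsplit(x, "|", fixed = TRUE)
  out[is.na(x) | x == ""] <- list(character(0))
  out
}

join_field <- function(x) {
  vapply(x, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) "" else paste(v, collapse = "|")
  }, "")
}

#' Read a complex catalog from TSV
#'
#' Expects a UTF-8 tab-separated file with a header row containing at least
#' `complex_id` and `members` (pipe-separated protein IDs); optional columns
#' `bait`, `source_db`, `pub_id`. Member order is discarded and duplicate
#' IDs within a row collapse to a set. Multi-valued provenance (pipe-
#' separated, aligned between `pub_id` and `source_db`) round-trips.
#'
#' @param path file path.
#' @return a `complex_catalog`.
#' @export
read_catalog_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          na.strings = character(0),
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("complex_id", "members")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("catalog TSV missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  members <- split_field(df$members)
  empty <- vapply(members, length, 1L) == 0L
  if (any(empty))
    stop("empty member list at data row(s): ",
         paste(which(empty), collapse = ", "))
  getcol <- function(nm) if (nm %in% names(df)) df[[nm]] else NULL
  bait <- getcol("bait")
  if (!is.null(bait)) bait[bait == ""] <- NA_character_
  prov <- function(nm) {
    col <- getcol(nm)
    if (is.null(col)) return(NULL)
    lapply(split_field(col), function(v) if (length(v)) v else NA_character_)
  }
  pub <- prov("pub_id"); db <- prov("source_db")
  if (!is.null(pub) && !is.null(db)) {
    # pad the shorter side of each multi-valued pair so pairs stay aligned
    k <- mapply(function(p, s) max(length(p), length(s)), pub, db)
    pub <- mapply(function(p, n) c(p, rep(NA_character_, n - length(p))),
                  pub, k, SIMPLIFY = FALSE)
    db <- mapply(function(s, n) c(s, rep(NA_character_, n - length(s))),
                 db, k, SIMPLIFY = FALSE)
  }
  tryCatch(
    complex_catalog(df$complex_id, members, bait, pub, db),
    error = function(e) stop("invalid catalog in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
}

#' Write a complex catalog to TSV
#'
#' Inverse of [read_catalog_tsv()]: member sets, baits and provenance
#' round-trip exactly (members are written sorted).
#'
#' @param catalog a `complex_catalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  df <- data.frame(
    complex_id = catalog$complex_id,
    members = join_field(catalog$members),
    bait = ifelse(is.na(catalog$bait), "", catalog$bait),
    source_db = join_field(catalog$source_db),
    pub_id = join_field(catalog$pub_id),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read complexes from a MITAB-style file
#'
#' Consolidated interaction databases distribute complex records in a
#' tab-delimited dialect in which a complex is spread over several rows:
#' an edge-type flag marks complex rows, the complex identifier sits in the
#' interactor-A column, and each row carries one member in the interactor-B
#' column. Column names and the flag value are configurable because the
#' encoding varies between sources. Non-complex (binary) rows are ignored
#' and counted; a file with no complex rows yields an empty catalog with a
#' warning, not an error.
#'
#' @param path file path (tab-separated, header row).
#' @param id_col column holding the complex identifier (interactor A).
#' @param member_col column holding one member per row (interactor B).
#' @param flag_col,flag_value column and value flagging complex rows.
#' @param role_col optional column with the experimental role of the
#'   interactor-B protein; rows whose role contains `"bait"` set the bait.
#' @param pub_col,db_col optional provenance columns.
#' @return a `complex_catalog`.
#' @export
read_mitab_complexes <- function(path, id_col = "interactor_a",
                                 member_col = "interactor_b",
                                 flag_col = "edge_type", flag_value = "C",
                                 role_col = "experimental_role_b",
                                 pub_col = "pub_id", db_col = "source_db") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          na.strings = character(0),
                          check.names = FALSE, fileEncoding = "UTF-8")
  for (cl in c(id_col, member_col, flag_col))
    if (!cl %in% names(df))
      stop("MITAB-style file missing column: ", cl)
  is_complex <- df[[flag_col]] == flag_value
  n_skipped <- sum(!is_complex)
  bad <- is_complex & (df[[id_col]] == "" | df[[member_col]] == "")
  if (any(bad)) {
    message("skipping ", sum(bad), " unparseable complex row(s) at line(s): ",
            paste(utils::head(which(bad) + 1L, 20), collapse = ", "))
    is_complex <- is_complex & !bad
  }
  cx <- df[is_complex, , drop = FALSE]
  if (!nrow(cx)) {
    warning("no complex rows found (", n_skipped, " non-complex rows ignored)")
    return(complex_catalog(character(0), list()))
  }
  ids <- unique(cx[[id_col]])
  members <- lapply(ids, function(i) cx[[member_col]][cx[[id_col]] == i])
  pick1 <- function(col, i) {
    if (is.null(col) || !col %in% names(cx)) return(NA_character_)
    v <- unique(cx[[col]][cx[[id_col]] == i])
    v <- v[v != ""]
    if (length(v)) v[1] else NA_character_
  }
  bait <- vapply(ids, function(i) {
    if (is.null(role_col) || !role_col %in% names(cx)) return(NA_character_)
    sel <- cx[[id_col]] == i & grepl("bait", cx[[role_col]], ignore.case = TRUE)
    if (any(sel)) cx[[member_col]][sel][1] else NA_character_
  }, "")
  pub <- vapply(ids, function(i) pick1(pub_col, i), "")
  db <- vapply(ids, function(i) pick1(db_col, i), "")
  message("read ", length(ids), " complex(es) from ", sum(is_complex),
          " complex rows; ignored ", n_skipped, " non-complex row(s)")
  complex_catalog(ids, members, bait, pub, db)
}

#' Merge records with identical member sets
#'
#' Consolidated catalogs are nonredundant by construction, but synthetic or
#' foreign catalogs may carry several records with exactly the same member
#' set. Such records are merged: the kept identifier is the
#' lexicographically smallest, and the provenance pairs of all merged
#' records are concatenated (multi-valued provenance), so "does this
#' complex come from more than one paper or database?" remains answerable.
#' Nested-pair orientation requires a deduplicated catalog (ties in size are
#' impossible once equal sets are merged).
#'
#' @param catalog a `complex_catalog`.
#' @return list with `catalog` (deduplicated) and `mapping` (named character
#'   vector removed_id -> kept_id; identity entries omitted).
#' @export
dedupe_catalog <- function(catalog) {
  key <- vapply(catalog$members, paste, "", collapse = "\r")
  grp <- split(seq_along(key), key)
  keep <- logical(length(key))
  mapping <- character(0)
  pub <- catalog$pub_id; db <- catalog$source_db
  bait <- catalog$bait
  for (idx in grp) {
    ids <- catalog$complex_id[idx]
    k <- idx[order(ids)][1]
    keep[k] <- TRUE
    others <- setdiff(idx, k)
    if (length(others)) {
      mapping[catalog$complex_id[others]] <- catalog$complex_id[k]
      pr <- cbind(unlist(pub[idx]), unlist(db[idx]))
      pr <- unique(pr[!(is.na(pr[, 1]) & is.na(pr[, 2])), , drop = FALSE])
      if (nrow(pr)) {
        pub[[k]] <- pr[, 1]; db[[k]] <- pr[, 2]
      }
      if (is.na(bait[k])) bait[k] <- stats::na.omit(c(bait[idx], NA))[1]
    }
  }
  out <- complex_catalog(catalog$complex_id[keep], catalog$members[keep],
                         bait[keep], pub[keep], db[keep])
  list(catalog = out, mapping = mapping)
}

#' Construct a protein annotation table
#'
#' Per-protein GO-like term sets for the three ontologies plus essentiality
#' and disease flags. Proteins absent from the table are treated downstream
#' as unannotated with both flags `FALSE`.
#'
#' @param protein_id character vector of protein IDs (unique).
#' @param go_bp,go_mf,go_cc lists of character vectors of term IDs (may be
#'   empty sets).
#' @param essential,disease logical vectors.
#' @return an object of class `annotation_table`.
#' @export
annotation_table <- function(protein_id, go_bp = NULL, go_mf = NULL,
                             go_cc = NULL, essential = NULL, disease = NULL) {
  n <- length(protein_id)
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id)) stop("duplicate protein_id")
  fix <- function(x) {
    if (is.null(x)) return(rep(list(character(0)), n))
    if (length(x) != n) stop("annotation fields must match protein_id length")
    lapply(x, function(v) sort(unique(as.character(v))))
  }
  flg <- function(x) {
    if (is.null(x)) return(rep(FALSE, n))
    if (length(x) != n) stop("annotation fields must match protein_id length")
    as.logical(x)
  }
  out <- list(protein_id = protein_id, go_bp = fix(go_bp), go_mf = fix(go_mf),
              go_cc = fix(go_cc), essential = flg(essential),
              disease = flg(disease))
  for (nm in c("go_bp", "go_mf", "go_cc", "essential", "disease"))
    names(out[[nm]]) <- protein_id
  structure(out, class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation_table: ", length(x$protein_id), " proteins; ",
      sum(x$essential), " essential, ", sum(x$disease), " disease\n", sep = "")
  invisible(x)
}

#' Read an annotation table from TSV
#'
#' Columns: `protein_id`, `go_bp`, `go_mf`, `go_cc` (pipe-separated term
#' IDs, empty allowed), `essential` and `disease` (0/1).
#'
#' @param path file path.
#' @return an `annotation_table`.
#' @export
read_annotations_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          na.strings = character(0),
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("protein_id", "go_bp", "go_mf", "go_cc", "essential", "disease")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation TSV missing column(s): ", paste(miss, collapse = ", "))
  annotation_table(df$protein_id, split_field(df$go_bp),
                   split_field(df$go_mf), split_field(df$go_cc),
                   df$essential == "1", df$disease == "1")
}

#' Write an annotation table to TSV
#' @param annotations an `annotation_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(annotations, path) {
  df <- data.frame(
    protein_id = annotations$protein_id,
    go_bp = join_field(annotations$go_bp),
    go_mf = join_field(annotations$go_mf),
    go_cc = join_field(annotations$go_cc),
    essential = as.integer(annotations$essential),
    disease = as.integer(annotations$disease),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
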