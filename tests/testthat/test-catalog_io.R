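test_that("catalog TSV rows map to records with set semantics", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("complex_id\tmembers\tbait\tsource_db\tpub_id",
               "cA\tP1|P2|P3\tP1\tdbX\tpm1",
               "cB\tP1|P1|P2\t\t\t"), tf)
  cat <- read_catalog_tsv(tf)
  expect_equal(length(cat), 2L)
  expect_setequal(cat$members$cA, c("P1", "P2", "P3"))
  expect_equal(cat$bait[["cA"]], "P1")
  expect_equal(cat$source_db$cA, "dbX")
  expect_equal(cat$pub_id$cA, "pm1")
  # duplicate members collapse to a set
  expect_setequal(cat$members$cB, c("P1", "P2"))
  expect_true(is.na(cat$bait[["cB"]]))
})

test_that("catalog reader rejects malformed input", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("complex_id\tbait", "cA\tP1"), tf)
  expect_error(read_catalog_tsv(tf), "members")
  writeLines(c("complex_id\tmembers", "cA\t"), tf)
  expect_error(read_catalog_tsv(tf), "empty member list")
  writeLines(c("complex_id\tmembers\tbait", "cA\tP1|P2\tP9"), tf)
  expect_error(read_catalog_tsv(tf), "bait")
  writeLines(c("complex_id\tmembers", "cA\tP1|P2", "cA\tP3|P4"), tf)
  expect_error(read_catalog_tsv(tf), "duplicate complex_id")
})

test_that("worked-example catalog has the expected protein universe", {
  # four HAT complexes: SAGA's 20 subunits plus RTG2 (from SLIK);
  # SALSA and ADA/GCN5 add nothing new
  cat <- hat_catalog()
  univ_oracle <- sort(unique(unlist(cat$members)))
  expect_equal(protein_universe(cat), univ_oracle)
  expect_length(protein_universe(cat), 21L)
  expect_true("RTG2" %in% protein_universe(cat))
  expect_setequal(setdiff(protein_universe(cat), cat$members$SAGA), "RTG2")
})

test_that("catalog TSV round-trips member sets, baits and provenance", {
  cat <- random_catalog(25, seed = 42, p_dup = 0.2)
  cat$bait[3] <- cat$members[[3]][1]
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_tsv(cat, tf)
  back <- read_catalog_tsv(tf)
  expect_equal(back$complex_id, cat$complex_id)
  expect_equal(back$members, cat$members)
  expect_equal(back$bait, cat$bait)
  expect_equal(back$pub_id, cat$pub_id)
  expect_equal(back$source_db, cat$source_db)
  # multi-valued provenance (post-dedupe) round-trips too
  dd <- dedupe_catalog(cat)$catalog
  write_catalog_tsv(dd, tf)
  back2 <- read_catalog_tsv(tf)
  expect_equal(back2$pub_id, dd$pub_id)
  expect_equal(back2$source_db, dd$source_db)
})

test_that("MITAB-style complex rows group into records", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "interactor_a\tinteractor_b\tedge_type\texperimental_role_b\tpub_id\tsource_db",
    "cplx:9\tP1\tC\tprey\tpm7\tdbZ",
    "cplx:9\tP2\tC\tbait\tpm7\tdbZ",
    "cplx:9\tP3\tC\tprey\tpm7\tdbZ",
    "cplx:4\tQ1\tC\t\tpm8\tdbZ",
    "cplx:4\tQ2\tC\t\tpm8\tdbZ",
    "cplx:4\tQ3\tC\t\tpm8\tdbZ",
    "cplx:4\tQ4\tC\t\tpm8\tdbZ",
    "P9\tP8\tX\t\tpm9\tdbZ"), tf)
  suppressMessages(cat <- read_mitab_complexes(tf))
  expect_equal(length(cat), 2L)
  expect_setequal(cat$members[["cplx:9"]], c("P1", "P2", "P3"))
  expect_equal(sort(complex_sizes(cat)), c(3L, 4L), ignore_attr = TRUE)
  expect_equal(cat$bait[["cplx:9"]], "P2")  # experimental role column
  expect_true(is.na(cat$bait[["cplx:4"]]))
  expect_equal(cat$pub_id[["cplx:9"]], "pm7")
})

test_that("MITAB file without complex rows warns and yields empty catalog", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("interactor_a\tinteractor_b\tedge_type",
               "P1\tP2\tX", "P2\tP3\tX"), tf)
  expect_warning(cat <- read_mitab_complexes(tf), "no complex rows")
  expect_equal(length(cat), 0L)
})

test_that("dedupe merges equal member sets and keeps provenance", {
  cat <- complex_catalog(c("c2", "c1", "c3"),
                         list(c("P1", "P2"), c("P2", "P1"), c("P3", "P4")),
                         pub_id = c("pm1", "pm2", "pm3"),
                         source_db = c("dbA", "dbB", "dbC"))
  dd <- dedupe_catalog(cat)
  expect_equal(sort(dd$catalog$complex_id), c("c1", "c3"))
  expect_equal(dd$mapping, c(c2 = "c1"))
  # both provenance pairs retained on the kept record
  prov <- paste(dd$catalog$pub_id$c1, dd$catalog$source_db$c1)
  expect_setequal(prov, c("pm1 dbA", "pm2 dbB"))
})

test_that("dedupe is idempotent and preserves the protein universe", {
  for (seed in 1:3) {
    cat <- random_catalog(30, seed = seed, p_dup = 0.3)
    dd1 <- dedupe_catalog(cat)
    expect_equal(protein_universe(dd1$catalog), protein_universe(cat))
    dd2 <- dedupe_catalog(dd1$catalog)
    expect_equal(dd2$catalog$complex_id, dd1$catalog$complex_id)
    expect_length(dd2$mapping, 0L)
  }
  # all-distinct catalog passes through untouched
  cat <- random_catalog(10, seed = 9, p_subset = 0, p_dup = 0)
  dd <- dedupe_catalog(cat)
  expect_equal(length(dd$catalog), 10L)
  expect_length(dd$mapping, 0L)
})

test_that("annotation TSV round-trips", {
  ann <- annotation_table(
    c("P1", "P2", "P3"),
    go_bp = list(c("BP1", "BP2"), character(0), "BP3"),
    go_mf = list("MF1", "MF2", character(0)),
    essential = c(TRUE, FALSE, TRUE),
    disease = c(FALSE, FALSE, TRUE))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_annotations_tsv(ann, tf)
  back <- read_annotations_tsv(tf)
  expect_equal(back$go_bp, ann$go_bp)
  expect_equal(back$go_mf, ann$go_mf)
  expect_equal(back$essential, ann$essential)
  expect_equal(back$disease, ann$disease)
})
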