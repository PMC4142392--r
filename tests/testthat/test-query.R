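# History, update and comparison queries over a handcrafted 3-release store.
#
# Release 1: the tiny snapshot (MI0000001 with MIMAT0000001/2, MI0000002 with
#   MIMAT0000003 'saa-miR-2', MI0000003 with MIMAT0000004 'sbb-miR-7').
# Release 2: MIMAT0000003 renamed to 'saa-miR-2-5p';
#   MIMAT0000004 renamed to 'sbb-miR-7-3p'.
# Release 3: MIMAT0000004 sequence end-shifted; MI0000001 merged into
#   MI0000002 (matures forwarded to MIMAT0000003); new record MI0000010
#   with MIMAT0000009 'scc-miR-3' added.
build_query_store <- local({
  store <- NULL
  function() {
    if (!is.null(store)) return(store)
    r1 <- tiny_snapshot("1.0")

    prec <- r1$precursors
    mat <- r1$matures
    mat[["MIMAT0000003"]]$name <- "saa-miR-2-5p"
    prec[["MI0000002"]]$mature_features$product <- "saa-miR-2-5p"
    mat[["MIMAT0000004"]]$name <- "sbb-miR-7-3p"
    prec[["MI0000003"]]$mature_features$product <- "sbb-miR-7-3p"
    r2 <- release_snapshot("2.0", prec, mat, validate = FALSE)

    prec3 <- prec
    mat3 <- mat
    p3 <- prec3[["MI0000003"]]
    prec3[["MI0000003"]]$mature_features$start <- p3$mature_features$start + 2L
    prec3[["MI0000003"]]$mature_features$end <- p3$mature_features$end + 2L
    mat3[["MIMAT0000004"]]$sequence <-
      substr(p3$sequence, p3$mature_features$start + 2L, p3$mature_features$end + 2L)
    dead <- list(dead_entry("MI0000001", "saa-mir-1", "MI0000002"),
                 dead_entry("MIMAT0000001", "saa-miR-1-5p", "MIMAT0000003"),
                 dead_entry("MIMAT0000002", "saa-miR-1-3p", "MIMAT0000003"))
    prec3[["MI0000001"]] <- NULL
    mat3[["MIMAT0000001"]] <- NULL
    mat3[["MIMAT0000002"]] <- NULL
    newp <- precursor_record(
      "MI0000010", "scc-mir-3", strrep("AGGUCCAU", 9),
      description = "Simulatus sccensis miR-3 stem-loop",
      mature_features = data.frame(mature_accession = "MIMAT0000009",
                                   product = "scc-miR-3", start = 5L, end = 26L,
                                   evidence = "experimental", stringsAsFactors = FALSE))
    prec3[["MI0000010"]] <- newp
    mat3[["MIMAT0000009"]] <- mature_record("MIMAT0000009", "scc-miR-3",
                                            substr(newp$sequence, 5, 26), "MI0000010")
    r3 <- release_snapshot("3.0", prec3, mat3, dead, validate = FALSE)

    dirs <- vapply(list(r1, r2, r3), function(s) {
      d <- tempfile(paste0("qrel", s$release_label))
      write_release(s, d)
      d
    }, "")
    names(dirs) <- c("1.0", "2.0", "3.0")
    store <<- build_store(dirs)
    store
  }
})

test_that("identifiers resolve by accession, sequence and historical name", {
  store <- build_query_store()
  expect_equal(resolve_identifier(store, "MIMAT0000003"),
               data.frame(accession = "MIMAT0000003", molecule_type = "mature",
                          stringsAsFactors = FALSE))
  seq3 <- store$states$sequence[store$states$accession == "MIMAT0000003"][1]
  hit <- resolve_identifier(store, seq3)
  expect_true("MIMAT0000003" %in% hit$accession)
  # a name that was only ever borne in release 1 still resolves
  expect_equal(resolve_identifier(store, "saa-miR-2")$accession, "MIMAT0000003")
  # case-insensitive fallback by default (catches both the mature and the
  # like-named precursor), strict on demand
  ci <- resolve_identifier(store, "SAA-MIR-2")
  expect_setequal(ci$accession, c("MI0000002", "MIMAT0000003"))
  expect_equal(resolve_identifier(store, "SAA-MIR-2",
                                  molecule_type = "mature")$accession,
               "MIMAT0000003")
  expect_equal(nrow(resolve_identifier(store, "SAA-MIR-2", ignore_case = FALSE)), 0)
  # release context restricts to the state of that release
  expect_equal(nrow(resolve_identifier(store, "sbb-miR-7", molecule_type = "mature",
                                       release_context = "3.0")), 0)
  expect_equal(resolve_identifier(store, "sbb-miR-7")$accession, "MIMAT0000004")
  # molecule filter
  expect_equal(nrow(resolve_identifier(store, "MI0000002", molecule_type = "mature")), 0)
})

test_that("update statuses cover current/updated/dead/merged/unknown", {
  store <- build_query_store()
  expect_equal(update_query(store, "saa-miR-2-5p")$status, "current")
  u <- update_query(store, "saa-miR-2")
  expect_equal(u$status, "updated-name")
  expect_equal(u$latest_name, "saa-miR-2-5p")
  # renamed in 2.0 then sequence-shifted in 3.0: original name sees both
  u2 <- update_query(store, "sbb-miR-7")
  expect_equal(u2$status, "updated-both")
  expect_equal(u2$latest_name, "sbb-miR-7-3p")
  # rename happened before the shift, so the 2.0 name sees only the sequence
  u3 <- update_query(store, "sbb-miR-7-3p", release_context = "2.0")
  expect_equal(u3$status, "updated-sequence")
  # merged accession chases the forward pointer to the terminal record
  um <- update_query(store, "MIMAT0000001")
  expect_equal(um$status, "merged")
  expect_match(um$matched_accession, "MIMAT0000003$")
  expect_equal(um$latest_name, "saa-miR-2-5p")
  expect_equal(update_query(store, "xyz")$status, "unknown")
})

test_that("batch update flags per-row and never throws", {
  store <- build_query_store()
  rows <- read_batch_queries(c(
    "query\tid_type\tmolecule_type\trelease",
    "saa-miR-2\tname\tmature\t",
    "MIMAT0000001\taccession\t\t",
    "definitely-not-a-mirna\t\t\t"))
  rep <- batch_update(store, rows)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$status, c("updated-name", "merged", "unknown"))
})

test_that("histories carry ordered timelines and terminal status", {
  store <- build_query_store()
  h <- history_query(store, "MIMAT0000004")[[1]]
  expect_equal(h$timeline$release_label, c("1.0", "2.0", "3.0"))
  expect_equal(h$timeline$change_types,
               c("ADDED", "NAME_CHANGE", "SEQUENCE_CHANGE"))
  expect_equal(h$current_status, "active")
  hm <- history_query(store, "MIMAT0000001")[[1]]
  expect_equal(hm$current_status, "merged-into:MIMAT0000003")
  expect_warning(expect_length(history_query(store, "nothing-here"), 0),
                 "does not resolve")
  # a record added in the only release it exists in has a 1-entry timeline
  h1 <- history_query(store, "MIMAT0000009")[[1]]
  expect_equal(nrow(h1$timeline), 1)
  expect_equal(h1$timeline$change_types, "ADDED")
})

test_that("release comparison categorizes records and respects direction", {
  store <- build_query_store()
  cmp <- compare_releases(store, "1.0", "3.0", molecule_type = "mature")
  expect_equal(cmp$added, "MIMAT0000009")
  expect_equal(cmp$removed_merged, c("MIMAT0000001", "MIMAT0000002"))
  expect_length(cmp$removed_deleted, 0)
  expect_equal(cmp$name_changed, c("MIMAT0000003", "MIMAT0000004"))
  expect_equal(cmp$sequence_changed, "MIMAT0000004")
  expect_length(cmp$unchanged, 0)
  expect_equal(unname(cmp$summary[["changed"]]), 2)
  # every accession active in either release appears in >= 1 set
  everyone <- unique(c(cmp$added, cmp$removed_deleted, cmp$removed_merged,
                       cmp$name_changed, cmp$sequence_changed,
                       cmp$relation_changed, cmp$unchanged))
  expect_length(everyone, 5)

  rev <- compare_releases(store, "3.0", "1.0", molecule_type = "mature")
  expect_equal(rev$added, c(cmp$removed_deleted, cmp$removed_merged))
  expect_equal(c(rev$removed_deleted, rev$removed_merged), cmp$added)

  self <- compare_releases(store, "2.0", "2.0", molecule_type = "both")
  expect_equal(unname(self$summary[["unchanged"]]),
               nrow(reconstruct_snapshot(store, "2.0")$state))
  expect_equal(sum(self$summary[c("added", "removed", "changed")]), 0)

  prec <- compare_releases(store, "1.0", "3.0", molecule_type = "precursor")
  expect_equal(prec$added, "MI0000010")
  expect_equal(prec$removed_merged, "MI0000001")
  expect_error(compare_releases(store, "1.0", "9.9"), "unknown release")

  scc_only <- compare_releases(store, "1.0", "3.0", species = "scc")
  expect_equal(unname(scc_only$summary[["added"]]), 1)
  expect_equal(sum(scc_only$summary) - scc_only$summary[["added"]], 0)
})
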