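# Change classification and release-to-release diffing.

test_that("classify_change detects each tracked field independently", {
  s <- list(name = "hsa-miR-1", sequence = "ACGUACGUACGUACGUACGUA",
            relations = "MI0000001")
  expect_equal(classify_change(s, s), character(0))
  expect_equal(classify_change(s, modifyList(s, list(name = "hsa-miR-1a"))),
               "NAME_CHANGE")
  expect_equal(classify_change(s, modifyList(s, list(sequence = "ACGU"))),
               "SEQUENCE_CHANGE")
  expect_equal(classify_change(s, modifyList(s, list(relations = "MI0000002"))),
               "RELATION_CHANGE")
  # relation comparison is set-valued, order-insensitive
  both <- modifyList(s, list(relations = "MI0000001;MI0000002"))
  flipped <- modifyList(s, list(relations = "MI0000002;MI0000001"))
  expect_equal(classify_change(both, flipped), character(0))
})

test_that("classify_change agrees with a brute-force field comparator", {
  set.seed(2024)
  for (i in 1:200) {
    old <- random_state()
    new <- random_state()
    expect_equal(classify_change(old, new), oracle_classify(old, new))
  }
})

test_that("self-comparison yields no events and reversed order errors", {
  snap <- tiny_snapshot("2.0")
  expect_equal(nrow(diff_releases(snap, snap)), 0)
  later <- tiny_snapshot("3.0")
  expect_error(diff_releases(later, tiny_snapshot("2.0")), "out of order")
})

test_that("an injected rename/shift/additions/merge transition is recovered exactly", {
  prev <- tiny_snapshot("1.0")
  # rename saa-mir-2's mature, shift sbb-miR-7 by 1 nt, add a new precursor
  # with its mature, merge MI0000001 (and matures) into MI0000002
  nxt_prec <- prev$precursors
  nxt_mat <- prev$matures
  nxt_mat[["MIMAT0000003"]]$name <- "saa-miR-2-5p"
  nxt_prec[["MI0000002"]]$mature_features$product <- "saa-miR-2-5p"
  p3 <- nxt_prec[["MI0000003"]]
  nxt_prec[["MI0000003"]]$mature_features$start <- p3$mature_features$start + 1L
  nxt_prec[["MI0000003"]]$mature_features$end <- p3$mature_features$end + 1L
  nxt_mat[["MIMAT0000004"]]$sequence <-
    substr(p3$sequence, p3$mature_features$start + 1L, p3$mature_features$end + 1L)
  newp <- precursor_record(
    "MI0000004", "saa-mir-9", strrep("AGGUCCAU", 9),
    description = "Simulatus saaensis miR-9 stem-loop",
    mature_features = data.frame(mature_accession = "MIMAT0000005",
                                 product = "saa-miR-9", start = 5L, end = 26L,
                                 evidence = "experimental", stringsAsFactors = FALSE))
  nxt_prec[["MI0000004"]] <- newp
  nxt_mat[["MIMAT0000005"]] <- mature_record(
    "MIMAT0000005", "saa-miR-9", substr(newp$sequence, 5, 26), "MI0000004")
  dead <- list(dead_entry("MI0000001", "saa-mir-1", "MI0000002"),
               dead_entry("MIMAT0000001", "saa-miR-1-5p", "MIMAT0000003"),
               dead_entry("MIMAT0000002", "saa-miR-1-3p", "MIMAT0000003"))
  nxt_prec[["MI0000001"]] <- NULL
  nxt_mat[["MIMAT0000001"]] <- NULL
  nxt_mat[["MIMAT0000002"]] <- NULL
  nxt <- release_snapshot("2.0", nxt_prec, nxt_mat, dead, validate = FALSE)

  ev <- diff_releases(prev, nxt)
  expect_equal(ev$accession,
               c("MI0000001", "MI0000004", "MIMAT0000001", "MIMAT0000002",
                 "MIMAT0000003", "MIMAT0000004", "MIMAT0000005"))
  got <- setNames(ev$change_types, ev$accession)
  expect_equal(unname(got[c("MI0000004", "MIMAT0000005")]), rep("ADDED", 2))
  expect_equal(unname(got[["MI0000001"]]), "MERGED")
  expect_equal(ev$merge_target[ev$accession == "MI0000001"], "MI0000002")
  expect_equal(unname(got[["MIMAT0000003"]]), "NAME_CHANGE")
  expect_equal(unname(got[["MIMAT0000004"]]), "SEQUENCE_CHANGE")
})

test_that("a re-issued name yields DELETED + ADDED, never a rename", {
  prev <- tiny_snapshot("1.0")
  nxt_prec <- prev$precursors
  nxt_mat <- prev$matures
  # retire MI0000002/MIMAT0000003 and re-issue the names to a new accession
  old_pname <- nxt_prec[["MI0000002"]]$name
  old_mname <- nxt_mat[["MIMAT0000003"]]$name
  dead <- list(dead_entry("MI0000002", old_pname), dead_entry("MIMAT0000003", old_mname))
  nxt_prec[["MI0000002"]] <- NULL
  nxt_mat[["MIMAT0000003"]] <- NULL
  newp <- precursor_record(
    "MI0000009", old_pname, strrep("CCAAUGGU", 9),
    mature_features = data.frame(mature_accession = "MIMAT0000009",
                                 product = old_mname, start = 5L, end = 26L,
                                 evidence = "experimental", stringsAsFactors = FALSE))
  nxt_prec[["MI0000009"]] <- newp
  nxt_mat[["MIMAT0000009"]] <- mature_record(
    "MIMAT0000009", old_mname, substr(newp$sequence, 5, 26), "MI0000009")
  nxt <- release_snapshot("2.0", nxt_prec, nxt_mat, dead, validate = FALSE)

  ev <- diff_releases(prev, nxt)
  got <- setNames(ev$change_types, ev$accession)
  expect_equal(unname(got[["MI0000002"]]), "DELETED")
  expect_equal(unname(got[["MI0000009"]]), "ADDED")
  expect_false(any(grepl("NAME_CHANGE", ev$change_types)))
})

test_that("diff output is deterministic and partitions the accession universe", {
  sim <- sim_fixture(17, n_initial_precursors = 20, n_releases = 4)
  snaps <- lapply(names(sim$dirs), function(l) load_release(sim$dirs[[l]], l))
  for (i in seq_len(length(snaps) - 1L)) {
    ev1 <- diff_releases(snaps[[i]], snaps[[i + 1L]])
    ev2 <- diff_releases(snaps[[i]], snaps[[i + 1L]])
    expect_identical(ev1, ev2)

    prev_acc <- state_table(snaps[[i]])$accession
    nxt_acc <- state_table(snaps[[i + 1L]])$accession
    gained <- ev1$accession[ev1$change_types %in% c("ADDED", "RESURRECTED")]
    lost <- ev1$accession[ev1$change_types %in% c("DELETED", "MERGED")]
    changed <- setdiff(ev1$accession, c(gained, lost))
    unchanged <- setdiff(intersect(prev_acc, nxt_acc), changed)
    parts <- list(gained, lost, changed, unchanged)
    expect_equal(sort(unlist(parts)), sort(union(prev_acc, nxt_acc)))
    for (a in seq_along(parts)) for (b in seq_along(parts)) {
      if (a < b) expect_length(intersect(parts[[a]], parts[[b]]), 0)
    }
  }
})

test_that("a resurrected accession is flagged RESURRECTED, not ADDED", {
  prev <- tiny_snapshot("1.0")
  # release 2: MI0000003 + its mature die
  mid_prec <- prev$precursors
  mid_mat <- prev$matures
  dead <- list(dead_entry("MI0000003", "sbb-mir-7"),
               dead_entry("MIMAT0000004", "sbb-miR-7"))
  mid_prec[["MI0000003"]] <- NULL
  mid_mat[["MIMAT0000004"]] <- NULL
  mid <- release_snapshot("2.0", mid_prec, mid_mat, dead, validate = FALSE)
  # release 3: they return unchanged
  nxt <- tiny_snapshot("3.0")
  ev <- diff_releases(mid, nxt)
  got <- setNames(ev$change_types, ev$accession)
  expect_equal(unname(got[["MI0000003"]]), "RESURRECTED")
  expect_equal(unname(got[["MIMAT0000004"]]), "RESURRECTED")
})
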