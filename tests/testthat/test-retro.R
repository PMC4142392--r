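# Retro-assignment of canonical accessions to pre-accession mature records.

# anchor with two matures; pre-release variants exercise each matching rule
retro_fixture <- function() {
  anchor <- tiny_snapshot("6.0")
  pre <- tiny_snapshot("5.1")
  # strip accessions: rebuild matures with provisional ids
  stripped <- lapply(pre$matures, function(m) {
    mature_record(mirtracker:::provisional_accession(m$species_code, m$name, m$sequence),
                  m$name, m$sequence, m$parent_precursors)
  })
  prec <- lapply(pre$precursors, function(p) {
    p$mature_features$mature_accession <- NA_character_
    p
  })
  pre <- release_snapshot("5.1", prec, stripped, validate = FALSE)
  list(pre = pre, anchor = anchor)
}

test_that("identically named records inherit the anchor accession via rule:name", {
  fx <- retro_fixture()
  map <- assign_retro_accessions(list(fx$pre), fx$anchor)
  expect_equal(nrow(map), 4)
  expect_true(all(map$provenance == "rule:name"))
  hit <- map[map$name == "saa-miR-1-5p", ]
  expect_equal(hit$accession, "MIMAT0000001")
})

test_that("renamed-but-sequence-identical records match via rule:sequence", {
  fx <- retro_fixture()
  pre <- fx$pre
  prov <- names(pre$matures)[vapply(pre$matures, function(m) m$name == "saa-miR-2", TRUE)]
  old <- pre$matures[[prov]]
  pre$matures[[prov]] <- mature_record(old$accession, "saa-miR-2-old-style",
                                       old$sequence, old$parent_precursors)
  map <- assign_retro_accessions(list(pre), fx$anchor)
  hit <- map[map$name == "saa-miR-2-old-style", ]
  expect_equal(hit$accession, "MIMAT0000003")
  expect_equal(hit$provenance, "rule:sequence")
})

test_that("unmatched records get stable provisional accessions", {
  fx <- retro_fixture()
  pre <- fx$pre
  ghost_prec <- precursor_record(
    "MI0000099", "saa-mir-99", strrep("UUGGCCAA", 9),
    mature_features = data.frame(mature_accession = NA_character_,
                                 product = "saa-miR-99", start = 3L, end = 24L,
                                 evidence = NA_character_, stringsAsFactors = FALSE))
  ghost_seq <- substr(ghost_prec$sequence, 3, 24)
  ghost <- mature_record(
    mirtracker:::provisional_accession("saa", "saa-miR-99", ghost_seq),
    "saa-miR-99", ghost_seq, "MI0000099")
  prec2 <- c(pre$precursors, list(ghost_prec))
  mat2 <- c(pre$matures, list(ghost))
  pre2 <- release_snapshot("5.1", prec2, mat2, validate = FALSE)

  map1 <- assign_retro_accessions(list(pre), fx$anchor)
  map2 <- assign_retro_accessions(list(pre2), fx$anchor)
  ghost_row <- map2[map2$name == "saa-miR-99", ]
  expect_equal(ghost_row$provenance, "provisional")
  expect_match(ghost_row$accession, "^PROV")
  # totality and injectivity
  expect_equal(nrow(map2), 5)
  expect_false(anyDuplicated(map2$accession) > 0)
  # retro-map stability: the unrelated addition did not disturb existing entries
  common <- map1[order(map1$name), ]
  rownames(common) <- NULL
  sub2 <- map2[map2$name != "saa-miR-99", ]
  sub2 <- sub2[order(sub2$name), ]
  rownames(sub2) <- NULL
  expect_identical(common, sub2)
  # and the provisional id itself is reproducible across rebuilds
  map3 <- assign_retro_accessions(list(pre2), fx$anchor)
  expect_identical(map2, map3)
})

test_that("overrides take precedence and unknown override accessions error", {
  fx <- retro_fixture()
  m <- fx$pre$matures[[1]]
  ov <- data.frame(release = "5.1", species_code = m$species_code, name = m$name,
                   sequence = m$sequence, accession = "MIMAT0000004",
                   stringsAsFactors = FALSE)
  map <- assign_retro_accessions(list(fx$pre), fx$anchor, overrides = ov)
  hit <- map[map$name == m$name & map$sequence == m$sequence, ]
  expect_equal(hit$accession, "MIMAT0000004")
  expect_equal(hit$provenance, "override")

  bad <- ov
  bad$accession <- "MIMAT9999999"
  expect_error(assign_retro_accessions(list(fx$pre), fx$anchor, overrides = bad),
               "MIMAT9999999")
})

test_that("overlap matching resolves end-shifted sequences and breaks ties by name", {
  fx <- retro_fixture()
  pre <- fx$pre
  prov <- names(pre$matures)[vapply(pre$matures, function(m) m$name == "sbb-miR-7", TRUE)]
  old <- pre$matures[[prov]]
  # shift the 5' end by 2 nt and rename: neither rule 1 nor 2 can fire
  p3 <- pre$precursors[["MI0000003"]]
  shifted <- substr(p3$sequence, 23, 44)
  pre$matures[[prov]] <- mature_record(old$accession, "sbb-miR-7-old", shifted,
                                       old$parent_precursors)
  pre$precursors[["MI0000003"]]$mature_features$start <- 23L
  map <- assign_retro_accessions(list(pre), fx$anchor)
  hit <- map[map$name == "sbb-miR-7-old", ]
  expect_equal(hit$accession, "MIMAT0000004")
  expect_equal(hit$provenance, "rule:overlap")
})

test_that("a full pre-accession series is recovered through the store build", {
  sim <- sim_fixture(29, n_initial_precursors = 15, n_releases = 5,
                     accession_epoch = 3, p_delete = 0, p_merge = 0,
                     p_resurrect = 0)
  # emitted early releases really lack MIMAT tokens
  fa <- readLines(file.path(sim$dirs[["1.0"]], "mature.fa"))
  expect_false(any(grepl("MIMAT", fa)))
  fa_late <- readLines(file.path(sim$dirs[["3.0"]], "mature.fa"))
  expect_true(any(grepl("MIMAT", fa_late)))

  store <- build_store(sim$dirs)
  expect_false(any(grepl("^PROV", store$changes$accession)))
  expect_identical(store_events(store), canonical_log(sim$log))
})
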