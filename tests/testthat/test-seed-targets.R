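# Seed extraction, canonical seed-match site scanning and the overlap ratio.

test_that("seed_of slices positions 2-8 and rejects short input", {
  expect_equal(seed_of("ACAAGUCAGGCUCUUGGGACCU"), "CAAGUCA")
  expect_error(seed_of("ACAAGUC"), "length 7")
  set.seed(7)
  for (i in 1:50) {
    n <- sample(8:30, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    expect_equal(seed_of(s), substr(s, 2, 8))
    expect_equal(seed_of(s, c(2, 7)), substr(s, 2, 7))
  }
})

test_that("site strings are the reverse complements the site types define", {
  m <- "ACAAGUCAGGCUCUUGGGACCU"  # seed CAAGUCA
  sites <- mirtracker:::site_strings(m)
  expect_equal(unname(sites["7mer-m8"]), oracle_revcomp("CAAGUCA"))
  expect_equal(unname(sites["7mer-m8"]), "UGACUUG")
  expect_equal(unname(sites["6mer"]), oracle_revcomp("CAAGUC"))
  expect_equal(unname(sites["7mer-A1"]), paste0(oracle_revcomp("CAAGUC"), "A"))
  expect_equal(unname(sites["8mer"]), paste0(oracle_revcomp("CAAGUCA"), "A"))
})

test_that("the scanner agrees with a brute-force window scan", {
  set.seed(11)
  for (i in 1:100) {
    m <- paste(sample(c("A", "C", "G", "U"), sample(19:24, 1), replace = TRUE),
               collapse = "")
    utr <- paste(sample(c("A", "C", "G", "U"), sample(30:200, 1), replace = TRUE),
                 collapse = "")
    pred <- predict_targets(stats::setNames(m, "m"), c(tx = utr))
    sites <- mirtracker:::site_strings(m)
    expected <- sum(vapply(sites, oracle_count_sites, 0L, utr = utr))
    if (expected == 0) {
      expect_equal(nrow(pred), 0)
    } else {
      expect_equal(pred$n_sites, expected)
      present <- names(sites)[vapply(sites, oracle_count_sites, 0L, utr = utr) > 0]
      expect_equal(strsplit(pred$site_types, ";")[[1]], present)
    }
  }
})

test_that("interactions deduplicate to (miRNA, transcript) pairs", {
  m <- "ACAAGUCAGGCUCUUGGGACCU"
  site <- mirtracker:::site_strings(m)[["7mer-m8"]]
  # two sites in one transcript -> one interaction, site count 2 (+ nested 6mers)
  utr <- paste0("GG", site, "CCAAA", site, "GG")
  pred <- predict_targets(stats::setNames(m, "m1"), c(tx = utr),
                          site_types = "7mer-m8")
  expect_equal(nrow(pred), 1)
  expect_equal(pred$n_sites, 2L)
  expect_equal(pred$site_types, "7mer-m8")
  # a UTR with no site yields no interaction
  expect_equal(nrow(predict_targets(stats::setNames(m, "m1"),
                                    c(tx = "AAAAAAAAAAAAAAAA"))), 0)
})

test_that("overlap ratio has the defining properties and the 1/3 example", {
  a <- data.frame(mirna_id = c("m1", "m1"), transcript_id = c("t1", "t2"))
  b <- data.frame(mirna_id = c("m1", "m1"), transcript_id = c("t2", "t3"))
  ov <- prediction_overlap(a, b)
  expect_equal(ov$n_common, 1L)
  expect_equal(ov$n_union, 3L)
  expect_equal(ov$ratio, 1 / 3)
  expect_equal(prediction_overlap(a, a)$ratio, 1)
  disjoint <- data.frame(mirna_id = "m9", transcript_id = "t9")
  expect_equal(prediction_overlap(a, disjoint)$ratio, 0)
  expect_error(prediction_overlap(a[0, ], b[0, ]), "undefined")
  expect_error(prediction_overlap(a, b, restrict_to = "m42"), "undefined")

  set.seed(5)
  for (i in 1:50) {
    mk <- function() {
      n <- sample(1:12, 1)
      data.frame(mirna_id = sample(paste0("m", 1:4), n, replace = TRUE),
                 transcript_id = sample(paste0("t", 1:6), n, replace = TRUE))
    }
    x <- mk(); y <- mk()
    rxy <- prediction_overlap(x, y)$ratio
    ryx <- prediction_overlap(y, x)$ratio
    expect_equal(rxy, ryx)   # symmetric
    expect_gte(rxy, 0)
    expect_lte(rxy, 1)
    keys <- function(d) unique(paste(d$mirna_id, d$transcript_id))
    expect_equal(rxy == 1, setequal(keys(x), keys(y)))  # 1 iff equal sets
  }
})

test_that("a seed change makes 7mer-m8 interaction sets disjoint on single-site UTRs", {
  old <- "ACAAGUCAGGCUCUUGGGACCU"
  new <- paste0(substr(old, 1, 3), "GGC", substr(old, 7, nchar(old)))  # seed changed
  expect_true(seed_of(old) != seed_of(new))
  s_old <- mirtracker:::site_strings(old)[["7mer-m8"]]
  s_new <- mirtracker:::site_strings(new)[["7mer-m8"]]
  utrs <- c(u_old = paste0("CGC", s_old, "CGC"), u_new = paste0("CGC", s_new, "CGC"))
  p_old <- predict_targets(stats::setNames(old, "m"), utrs, site_types = "7mer-m8")
  p_new <- predict_targets(stats::setNames(new, "m"), utrs, site_types = "7mer-m8")
  expect_equal(p_old$transcript_id, "u_old")
  expect_equal(p_new$transcript_id, "u_new")
  expect_equal(prediction_overlap(p_old, p_new)$ratio, 0)
})

# two-release store in which one mature changes inside the seed and another
# changes outside positions 1-8
impact_fixture <- function() {
  r1 <- tiny_snapshot("1.0")
  prec <- r1$precursors
  mat <- r1$matures
  mutate_at <- function(seq, pos) {
    base <- substr(seq, pos, pos)
    repl <- setdiff(c("A", "C", "G", "U"), base)[1]
    paste0(substr(seq, 1, pos - 1), repl, substr(seq, pos + 1, nchar(seq)))
  }
  # MIMAT0000003 (feature 11..32 of MI0000002): hit mature position 4 (seed)
  p2 <- prec[["MI0000002"]]
  g <- p2$mature_features$start + 3L
  prec[["MI0000002"]]$sequence <- mutate_at(p2$sequence, g)
  mat[["MIMAT0000003"]]$sequence <-
    substr(prec[["MI0000002"]]$sequence, p2$mature_features$start, p2$mature_features$end)
  # MIMAT0000004 (feature 21..44 of MI0000003): hit mature position 15
  p3 <- prec[["MI0000003"]]
  g3 <- p3$mature_features$start + 14L
  prec[["MI0000003"]]$sequence <- mutate_at(p3$sequence, g3)
  mat[["MIMAT0000004"]]$sequence <-
    substr(prec[["MI0000003"]]$sequence, p3$mature_features$start, p3$mature_features$end)
  r2 <- release_snapshot("2.0", prec, mat, validate = FALSE)
  dirs <- vapply(list(r1, r2), function(s) {
    d <- tempfile("impact")
    write_release(s, d)
    d
  }, "")
  names(dirs) <- c("1.0", "2.0")
  build_store(dirs)
}

test_that("impact_report flags seed changes and scores per-miRNA overlap", {
  store <- impact_fixture()
  s1 <- reconstruct_snapshot(store, "1.0")$state
  s2 <- reconstruct_snapshot(store, "2.0")$state
  seqs <- function(st, acc) st$sequence[st$accession == acc]
  # UTRs engineered to contain exactly one 7mer-m8 site per sequence version
  mk_site <- function(seq) mirtracker:::site_strings(seq)[["7mer-m8"]]
  utrs <- c(
    a_old = paste0("CCC", mk_site(seqs(s1, "MIMAT0000003")), "CCC"),
    a_new = paste0("CCC", mk_site(seqs(s2, "MIMAT0000003")), "CCC"),
    b_old = paste0("CCC", mk_site(seqs(s1, "MIMAT0000004")), "CCC"))
  rep <- impact_report(store, "1.0", "2.0", utrs, site_types = "7mer-m8")
  tab <- rep$table
  expect_equal(sort(tab$accession), c("MIMAT0000003", "MIMAT0000004"))
  expect_equal(tab$seed_changed[tab$accession == "MIMAT0000003"], TRUE)
  expect_equal(tab$seed_changed[tab$accession == "MIMAT0000004"], FALSE)
  # seed-changed record: old and new predictions are disjoint
  expect_equal(tab$overlap_ratio[tab$accession == "MIMAT0000003"], 0)
  # change outside positions 1-8 preserves every 7mer-m8 site string
  expect_equal(tab$overlap_ratio[tab$accession == "MIMAT0000004"], 1)
  expect_true(rep$nonoverlap_pct > 0 && rep$nonoverlap_pct < 100)

  # releases with no sequence change produce an empty report with a note
  expect_message(empty <- impact_report(store, "1.0", "1.0", utrs),
                 "no mature sequence changes")
  expect_equal(nrow(empty$table), 0)
})
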