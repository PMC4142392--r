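# Fixtures are built in code: tiny handcrafted snapshots for exact-value
# tests, simulated series for property-style tests, plus independent oracles
# kept deliberately naive (they must not share code with the implementation).

# three-precursor snapshot with known coordinates and sequences
tiny_snapshot <- function(label = "1.0") {
  p1 <- precursor_record(
    accession = "MI0000001", name = "saa-mir-1",
    sequence = paste0("ACGUACGUAC", "GUACGUACGU", "AAACCCGGGU", "UUACGUACGU",
                      "ACGUACGUAC", "GUACGUACGU"),
    description = "Simulatus saaensis miR-1 stem-loop",
    mature_features = data.frame(
      mature_accession = c("MIMAT0000001", "MIMAT0000002"),
      product = c("saa-miR-1-5p", "saa-miR-1-3p"),
      start = c(3L, 35L), end = c(24L, 56L), evidence = "experimental",
      stringsAsFactors = FALSE))
  p2 <- precursor_record(
    accession = "MI0000002", name = "saa-mir-2",
    sequence = strrep("ACGGUUCA", 10),
    description = "Simulatus saaensis miR-2 stem-loop",
    mature_features = data.frame(
      mature_accession = "MIMAT0000003", product = "saa-miR-2",
      start = 11L, end = 32L, evidence = "experimental",
      stringsAsFactors = FALSE))
  p3 <- precursor_record(
    accession = "MI0000003", name = "sbb-mir-7",
    sequence = strrep("GAUCCAUG", 12),
    description = "Simulatus sbbensis miR-7 stem-loop",
    mature_features = data.frame(
      mature_accession = "MIMAT0000004", product = "sbb-miR-7",
      start = 21L, end = 44L, evidence = "experimental",
      stringsAsFactors = FALSE))
  mat <- function(p, i) {
    ft <- p$mature_features
    mature_record(ft$mature_accession[i], ft$product[i],
                  substr(p$sequence, ft$start[i], ft$end[i]), p$accession)
  }
  release_snapshot(label, list(p1, p2, p3),
                   list(mat(p1, 1), mat(p1, 2), mat(p2, 1), mat(p3, 1)))
}

# simulate a small series and return (dirs, log, store-ready label map)
sim_fixture <- function(seed, ..., dir = tempfile("simseries")) {
  simulate_release_series(simulation_params(rng_seed = seed, ...), dir)
}

# ground-truth log reduced to the event columns, in the diff engine's order
canonical_log <- function(log) {
  gt <- log[, c("release_label", "accession", "molecule_type", "change_types",
                "merge_target")]
  ord <- order(vapply(gt$release_label,
                      function(l) { o <- release_ordinal(l); o[1] * 1000 + o[2] }, 0),
               gt$accession, method = "radix")
  gt <- gt[ord, , drop = FALSE]
  rownames(gt) <- NULL
  gt
}

# --- independent oracles -------------------------------------------------

# reverse complement by explicit pairing table and rev()
oracle_revcomp <- function(s) {
  pairs <- c(A = "U", C = "G", G = "C", U = "A", N = "N")
  paste(rev(unname(pairs[strsplit(s, "")[[1]]])), collapse = "")
}

# count (possibly overlapping) occurrences of `site` in `utr` by scanning
# every window
oracle_count_sites <- function(site, utr) {
  w <- nchar(site)
  n <- nchar(utr)
  if (n < w) return(0L)
  sum(vapply(seq_len(n - w + 1L),
             function(i) substr(utr, i, i + w - 1L) == site, TRUE))
}

# brute-force field-by-field comparator for record states
oracle_classify <- function(old, new) {
  out <- character(0)
  if (old$name != new$name) out <- c(out, "NAME_CHANGE")
  if (old$sequence != new$sequence) out <- c(out, "SEQUENCE_CHANGE")
  rel <- function(x) sort(strsplit(x, ";", fixed = TRUE)[[1]])
  if (!identical(rel(old$relations), rel(new$relations))) {
    out <- c(out, "RELATION_CHANGE")
  }
  out
}

random_state <- function() {
  list(name = sample(c("hsa-miR-1", "hsa-miR-1a", "hsa-miR-1-5p"), 1),
       sequence = paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
                        collapse = ""),
       relations = paste(sample(c("MI0000001", "MI0000002", "MI0000003"),
                                sample(1:2, 1)), collapse = ";"))
}
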