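# Canonical seed-match target prediction and the prediction-overlap ratio.
#
# The functional impact of a mature-sequence revision is quantified by
# predicting 3'UTR target sites for both sequence versions and computing the
# ratio of common (miRNA, transcript) interactions to the union of unique
# interactions from both versions. Site definitions follow the canonical
# seed-match types: the seed is mature positions 2-8, sites are exact
# Watson-Crick reverse complements in the UTR (no G:U wobble), and an
# interaction is a deduplicated (miRNA, transcript) pair regardless of how
# many sites support it.

SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Extract the seed region of a mature miRNA sequence
#'
#' @param sequence mature RNA sequence (length >= the last seed position).
#' @param span integer pair, 1-based inclusive positions; the seed convention
#'   is positions 2-8.
#' @return the seed substring.
#' @export
#' @examples
#' seed_of("ACAAGUCAGGCUCUUGGGACCU")  # "CAAGUCA"
seed_of <- function(sequence, span = c(2L, 8L)) {
  if (nchar(sequence) < span[2L]) {
    stop(sprintf("sequence of length %d has no positions %d..%d",
                 nchar(sequence), span[1L], span[2L]), call. = FALSE)
  }
  substr(sequence, span[1L], span[2L])
}

# the four canonical site strings searched for in the UTR (5'->3')
site_strings <- function(mature_sequence) {
  rc27 <- rna_revcomp(seed_of(mature_sequence, c(2L, 7L)))
  rc28 <- rna_revcomp(seed_of(mature_sequence, c(2L, 8L)))
  c("6mer" = rc27,
    "7mer-A1" = paste0(rc27, "A"),
    "7mer-m8" = rc28,
    "8mer" = paste0(rc28, "A"))
}

#' Predict seed-match target interactions in a set of 3'UTRs
#'
#' Site types: `6mer` is the reverse complement of seed positions 2-7;
#' `7mer-m8` of positions 2-8; `7mer-A1` is the 6mer followed by an A in the
#' UTR opposite miRNA position 1; `8mer` is the 7mer-m8 plus that A.
#' Overlapping occurrences each count towards the site count. An interaction
#' is emitted when any requested site type occurs; interactions are unique
#' (miRNA, transcript) pairs.
#'
#' @param matures named character vector of mature sequences (names are the
#'   miRNA ids), or a data.frame with `accession`/`name` and `sequence`
#'   columns.
#' @param utrs named character vector of 3'UTR sequences (T is normalized to
#'   U), a `Biostrings::XStringSet`, or the path of a FASTA file.
#' @param site_types subset of `c("6mer", "7mer-A1", "7mer-m8", "8mer")`.
#' @return data.frame with columns `mirna_id`, `transcript_id`, `site_types`
#'   (`;`-joined subset found) and `n_sites`.
#' @export
predict_targets <- function(matures, utrs, site_types = SITE_TYPES) {
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  if (is.data.frame(matures)) {
    ids <- if ("accession" %in% names(matures)) matures$accession else matures$name
    matures <- stats::setNames(matures$sequence, ids)
  }
  if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs) &&
      is.null(names(utrs))) {
    utrs <- Biostrings::readBStringSet(utrs)
  }
  if (inherits(utrs, "XStringSet")) {
    utrs <- stats::setNames(as.character(utrs), names(utrs))
  }
  if (length(utrs) == 0L) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_types = character(0), n_sites = integer(0),
                      stringsAsFactors = FALSE))
  }
  utr_names <- sub("\\s.*$", "", names(utrs))
  subjects <- Biostrings::RNAStringSet(normalize_rna(unname(utrs), "UTR sequence"))

  out <- list()
  for (mid in names(matures)) {
    sites <- site_strings(matures[[mid]])[site_types]
    counts <- matrix(0L, nrow = length(subjects), ncol = length(sites),
                     dimnames = list(NULL, names(sites)))
    for (st in names(sites)) {
      counts[, st] <- Biostrings::vcountPattern(sites[[st]], subjects)
    }
    total <- rowSums(counts)
    hit <- which(total > 0L)
    for (h in hit) {
      present <- colnames(counts)[counts[h, ] > 0L]
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = mid, transcript_id = utr_names[h],
        site_types = paste(present, collapse = ";"),
        n_sites = as.integer(total[h]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_types = character(0), n_sites = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order_c(res$mirna_id, res$transcript_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

interaction_keys <- function(interactions) {
  unique(paste(interactions$mirna_id, interactions$transcript_id, sep = "\r"))
}

#' Prediction overlap between two interaction sets
#'
#' The overlap ratio is the number of common (miRNA, transcript) interactions
#' divided by the total number of unique interactions predicted in either set.
#' It is symmetric, lies in `[0, 1]`, and equals 1 exactly when the sets are
#' equal. An empty union is undefined and raises an error.
#'
#' @param set_a,set_b interaction data.frames from [predict_targets()].
#' @param restrict_to optional character vector of miRNA ids; both sets are
#'   filtered to these ids before the ratio is computed (used to restrict the
#'   statistic to records whose sequence changed).
#' @return an `overlap_result` list with `n_common`, `n_union`, `ratio` and
#'   `restricted_mirna_set`.
#' @export
prediction_overlap <- function(set_a, set_b, restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    set_a <- set_a[set_a$mirna_id %in% restrict_to, , drop = FALSE]
    set_b <- set_b[set_b$mirna_id %in% restrict_to, , drop = FALSE]
  }
  ka <- interaction_keys(set_a)
  kb <- interaction_keys(set_b)
  n_union <- length(union(ka, kb))
  if (n_union == 0L) {
    stop("overlap undefined: no interactions in either set after restriction",
         call. = FALSE)
  }
  n_common <- length(intersect(ka, kb))
  structure(list(n_common = n_common, n_union = n_union,
                 ratio = n_common / n_union,
                 restricted_mirna_set = restrict_to),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("prediction overlap: %d common / %d unique interactions = %.4f (%.1f%% nonoverlap)\n",
              x$n_common, x$n_union, x$ratio, 100 * (1 - x$ratio)))
  invisible(x)
}

#' Impact of sequence annotation changes on target prediction
#'
#' Selects the mature records common to `release_a` and `release_b` whose
#' sequences differ, predicts seed-match targets for both sequence versions,
#' and reports per-miRNA whether the seed (positions 2-8) changed together
#' with the per-miRNA overlap ratio, plus the aggregate overlap ratio and the
#' nonoverlap percentage `100 * (1 - ratio)` over the pooled interaction sets
#' (restricted to the sequence-changed records, matching the definition of
#' differential prediction attributable to sequence changes alone).
#'
#' @param store an `event_store`.
#' @param release_a,release_b registered release labels.
#' @param utrs 3'UTR set as accepted by [predict_targets()].
#' @param site_types site types to scan for.
#' @param species optional species-code filter.
#' @return an `impact_report` list with `table` (per-miRNA rows), `overlap`
#'   (the aggregate `overlap_result`, `NULL` when no record changed) and
#'   `nonoverlap_pct`.
#' @export
impact_report <- function(store, release_a, release_b, utrs,
                          site_types = SITE_TYPES, species = NULL) {
  store_check_release(store, release_a)
  store_check_release(store, release_b)
  sa <- reconstruct_snapshot(store, release_a)$state
  sb <- reconstruct_snapshot(store, release_b)$state
  sa <- sa[sa$molecule_type == "mature", , drop = FALSE]
  sb <- sb[sb$molecule_type == "mature", , drop = FALSE]
  if (!is.null(species)) {
    sa <- sa[sa$species_code == species, , drop = FALSE]
    sb <- sb[sb$species_code == species, , drop = FALSE]
  }
  common <- intersect(sa$accession, sb$accession)
  ia <- match(common, sa$accession)
  ib <- match(common, sb$accession)
  changed <- common[sa$sequence[ia] != sb$sequence[ib]]
  if (!length(changed)) {
    message(sprintf("no mature sequence changes between releases %s and %s",
                    release_a, release_b))
    return(structure(list(table = data.frame(), overlap = NULL,
                          nonoverlap_pct = NA_real_),
                     class = "impact_report"))
  }
  seq_a <- stats::setNames(sa$sequence[match(changed, sa$accession)], changed)
  seq_b <- stats::setNames(sb$sequence[match(changed, sb$accession)], changed)
  pred_a <- predict_targets(seq_a, utrs, site_types)
  pred_b <- predict_targets(seq_b, utrs, site_types)

  per <- do.call(rbind, lapply(changed, function(acc) {
    ratio <- tryCatch(
      prediction_overlap(pred_a, pred_b, restrict_to = acc)$ratio,
      error = function(e) NA_real_)  # no predictions for either version
    data.frame(
      accession = acc,
      name = sb$name[match(acc, sb$accession)],
      sequence_a = seq_a[[acc]], sequence_b = seq_b[[acc]],
      seed_changed = seed_of(seq_a[[acc]]) != seed_of(seq_b[[acc]]),
      overlap_ratio = ratio, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  overlap <- tryCatch(prediction_overlap(pred_a, pred_b, restrict_to = changed),
                      error = function(e) NULL)
  structure(list(
    release_a = release_a, release_b = release_b,
    table = per, overlap = overlap,
    nonoverlap_pct = if (is.null(overlap)) NA_real_ else 100 * (1 - overlap$ratio)
  ), class = "impact_report")
}

#' @export
print.impact_report <- function(x, ...) {
  if (!nrow(x$table)) {
    cat("impact report: no sequence-changed mature records between the releases\n")
    return(invisible(x))
  }
  cat(sprintf("impact of sequence changes %s -> %s: %d mature record(s) changed, %d with a seed change\n",
              x$release_a, x$release_b, nrow(x$table), sum(x$table$seed_changed)))
  if (!is.null(x$overlap)) print(x$overlap)
  invisible(x)
}
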