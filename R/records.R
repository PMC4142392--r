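# Record and snapshot constructors with invariant validation.
#
# A release snapshot is the complete annotation state of one miRBase release:
# precursor (stem-loop, "MI" accessions) records, mature ("MIMAT" accessions)
# records, and the cumulative list of dead (removed) entries.

#' Construct a precursor (stem-loop) record
#'
#' @param accession precursor accession ("MI" + 7 digits).
#' @param name precursor name, e.g. `"dme-mir-1"` (lowercase "mir" convention).
#' @param sequence precursor RNA sequence; normalized to uppercase, T to U.
#' @param description free-text description line; the species binomial is taken
#'   from its first two words when `species_name` is not given.
#' @param species_name binomial species name, e.g. `"Drosophila melanogaster"`.
#' @param mature_features data.frame with columns `mature_accession` (may be
#'   `NA` for releases predating mature accessions), `product`, `start`, `end`
#'   (1-based inclusive coordinates on the precursor) and `evidence`.
#' @param annotations character vector of verbatim annotation lines (literature
#'   references, database cross-references) retained opaquely.
#' @return an object of class `precursor_record`.
#' @export
precursor_record <- function(accession, name, sequence, description = "",
                             species_name = NA_character_,
                             mature_features = empty_features(),
                             annotations = character(0)) {
  sequence <- normalize_rna(sequence, sprintf("precursor %s sequence", accession))
  if (!grepl("^MI\\d{7}$", accession)) {
    stop(sprintf("invalid precursor accession '%s'", accession), call. = FALSE)
  }
  if (is.na(species_name) && nzchar(description)) {
    words <- strsplit(trimws(description), "\\s+")[[1]]
    if (length(words) >= 2L) species_name <- paste(words[1:2], collapse = " ")
  }
  mature_features <- as.data.frame(mature_features, stringsAsFactors = FALSE)
  len <- nchar(sequence)
  if (nrow(mature_features) > 0L) {
    bad <- mature_features$start < 1L | mature_features$end > len |
      mature_features$start > mature_features$end
    if (any(bad)) {
      stop(sprintf("precursor %s: feature coordinates outside 1..%d", accession, len),
           call. = FALSE)
    }
  }
  structure(list(
    accession = accession,
    name = name,
    species_code = species_of(name),
    species_name = species_name,
    description = description,
    sequence = sequence,
    length_nt = len,
    mature_features = mature_features,
    annotations = annotations
  ), class = "precursor_record")
}

empty_features <- function() {
  data.frame(mature_accession = character(0), product = character(0),
             start = integer(0), end = integer(0), evidence = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a mature miRNA record
#'
#' @param accession mature accession ("MIMAT" + 7 digits) or a provisional
#'   identifier ("PROV" prefix) for records predating mature accessions.
#' @param name mature name, e.g. `"rno-miR-292-5p"` ("miR" capitalization).
#' @param sequence mature RNA sequence (non-empty).
#' @param parent_precursors character vector of parent precursor accessions.
#' @param provisional logical; `TRUE` when the accession is a retro-assignment
#'   placeholder rather than a canonical miRBase accession.
#' @return an object of class `mature_record`.
#' @export
mature_record <- function(accession, name, sequence, parent_precursors,
                          provisional = startsWith(accession, "PROV")) {
  sequence <- normalize_rna(sequence, sprintf("mature %s sequence", accession))
  if (!nzchar(sequence)) stop("mature sequence must be non-empty", call. = FALSE)
  if (!grepl("^(MIMAT\\d{7}|PROV\\d+)$", accession)) {
    stop(sprintf("invalid mature accession '%s'", accession), call. = FALSE)
  }
  structure(list(
    accession = accession,
    name = name,
    species_code = species_of(name),
    sequence = sequence,
    parent_precursors = sort_c(unique(parent_precursors)),
    provisional = isTRUE(provisional)
  ), class = "mature_record")
}

#' Construct a dead (removed) entry
#'
#' @param accession accession of the removed record.
#' @param last_name the name it bore when removed.
#' @param forward_to accession it was merged into, or `NA` for plain deletion.
#' @param comment free-text comment.
#' @return an object of class `dead_entry`.
#' @export
dead_entry <- function(accession, last_name = NA_character_,
                       forward_to = NA_character_, comment = NA_character_) {
  if (!is.na(forward_to) && identical(forward_to, accession)) {
    stop(sprintf("dead entry %s forwards to itself", accession), call. = FALSE)
  }
  structure(list(
    accession = accession,
    last_name = last_name,
    forward_to = forward_to,
    comment = comment,
    molecule_type = if (startsWith(accession, "MIMAT")) "mature" else "precursor"
  ), class = "dead_entry")
}

#' Assemble a release snapshot
#'
#' Validates the cross-record invariants: unique accessions, every mature's
#' parent precursors present, mature sequences matching precursor substrings at
#' the linked feature coordinates (violations are surfaced as warnings, with
#' the mature sequence authoritative), and no accession simultaneously active
#' and dead.
#'
#' @param release_label version string, e.g. `"5.1"`, `"9.2"`, `"21"`.
#' @param precursors list of [precursor_record()] objects.
#' @param matures list of [mature_record()] objects.
#' @param dead list of [dead_entry()] objects, cumulative to this release.
#' @param release_date optional date string.
#' @param validate logical; check feature/substring consistency.
#' @return an object of class `release_snapshot` with accession-keyed
#'   `precursors` and `matures` maps.
#' @export
release_snapshot <- function(release_label, precursors = list(), matures = list(),
                             dead = list(), release_date = NA_character_,
                             validate = TRUE) {
  pacc <- vapply(precursors, `[[`, "", "accession")
  macc <- vapply(matures, `[[`, "", "accession")
  if (anyDuplicated(pacc)) stop("duplicate precursor accessions in snapshot", call. = FALSE)
  if (anyDuplicated(macc)) stop("duplicate mature accessions in snapshot", call. = FALSE)
  names(precursors) <- pacc
  names(matures) <- macc
  precursors <- precursors[sort_c(pacc)]
  matures <- matures[sort_c(macc)]
  dead_acc <- vapply(dead, `[[`, "", "accession")
  clash <- intersect(dead_acc, c(pacc, macc))
  if (length(clash)) {
    stop(sprintf("accessions both active and dead in release %s: %s",
                 release_label, paste(clash, collapse = ", ")), call. = FALSE)
  }
  snap <- structure(list(
    release_label = as.character(release_label),
    ordinal = release_ordinal(release_label),
    release_date = release_date,
    precursors = precursors,
    matures = matures,
    dead = dead
  ), class = "release_snapshot")
  if (validate) {
    for (m in matures) {
      missing_parent <- setdiff(m$parent_precursors, names(precursors))
      if (length(missing_parent)) {
        stop(sprintf("mature %s references absent precursor(s): %s",
                     m$accession, paste(missing_parent, collapse = ", ")),
             call. = FALSE)
      }
      if (!feature_sequence_consistent(snap, m)) {
        warning(sprintf(
          "release %s: mature %s sequence does not match any parent feature substring (mature.fa kept)",
          release_label, m$accession), call. = FALSE)
      }
    }
  }
  snap
}

# TRUE when the mature sequence equals the precursor substring at the linked
# feature coordinates for at least one parent.
feature_sequence_consistent <- function(snapshot, mature) {
  for (pa in mature$parent_precursors) {
    p <- snapshot$precursors[[pa]]
    ft <- p$mature_features
    rows <- which(ft$mature_accession %in% mature$accession |
                    ft$product == mature$name)
    for (i in rows) {
      if (substr(p$sequence, ft$start[i], ft$end[i]) == mature$sequence) return(TRUE)
    }
  }
  length(mature$parent_precursors) == 0L
}

#' Tracked-annotation projection of a snapshot
#'
#' Flattens a snapshot to one row per active record with the fields the event
#' store tracks: accession, molecule type, name, sequence, species code and
#' relations (parent precursors for matures, mature products for precursors,
#' as a sorted `;`-joined set). This is the equality basis for event replay.
#'
#' @param snapshot a `release_snapshot`.
#' @return data.frame sorted by accession.
#' @export
state_table <- function(snapshot) {
  prec <- snapshot$precursors
  mat <- snapshot$matures
  df <- data.frame(
    accession = c(names(prec), names(mat)),
    molecule_type = c(rep("precursor", length(prec)), rep("mature", length(mat))),
    name = c(vapply(prec, `[[`, "", "name"), vapply(mat, `[[`, "", "name")),
    sequence = c(vapply(prec, `[[`, "", "sequence"), vapply(mat, `[[`, "", "sequence")),
    species_code = c(vapply(prec, `[[`, "", "species_code"),
                     vapply(mat, `[[`, "", "species_code")),
    relations = c(
      vapply(prec, function(p) join_set(p$mature_features$mature_accession), ""),
      vapply(mat, function(m) join_set(m$parent_precursors), "")
    ),
    stringsAsFactors = FALSE
  )
  df <- df[order_c(df$accession), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.release_snapshot <- function(x, ...) {
  cat(sprintf("miRBase release snapshot %s: %d precursors, %d matures, %d dead entries\n",
              x$release_label, length(x$precursors), length(x$matures), length(x$dead)))
  invisible(x)
}

#' @export
print.precursor_record <- function(x, ...) {
  cat(sprintf("<precursor %s '%s' (%s), %d nt, %d mature feature(s)>\n",
              x$accession, x$name, x$species_code, x$length_nt, nrow(x$mature_features)))
  invisible(x)
}

#' @export
print.mature_record <- function(x, ...) {
  cat(sprintf("<mature %s '%s' %s, parents: %s>\n", x$accession, x$name,
              x$sequence, paste(x$parent_precursors, collapse = ",")))
  invisible(x)
}
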