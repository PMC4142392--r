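# Replayable event store.
#
# Two-table logical schema:
#   CHANGES(event_id, accession, molecule_type, change_type, release_label,
#           merge_target) -- one row per change type
#   STATES(event_id, accession, name, sequence, species_code, relations,
#          release_label)  -- the annotation after the change
# plus a release registry and the retro-accession provenance table. Any
# ingested release can be reconstructed exactly by replaying events in ordinal
# order from an empty state.

#' Build an event store from a series of release directories
#'
#' Loads each directory with [load_release()], orders snapshots numerically on
#' their (major, minor) ordinals, retro-assigns canonical accessions to
#' pre-accession mature records when needed (the anchor is the earliest
#' release whose matures all carry accessions), diffs the first release
#' against an empty snapshot (everything `ADDED`) and then every consecutive
#' pair, and concatenates the events. The build records input file checksums
#' in a manifest and is idempotent: rebuilding from identical inputs yields an
#' identical store.
#'
#' @param release_dirs named character vector: `release_label = directory`, or
#'   a list of `(directory, label)` pairs.
#' @param overrides optional retro-assignment overrides data.frame (columns
#'   `release`, `species_code`, `name`, `sequence`, `accession`) or the path
#'   of such a TSV.
#' @return an object of class `event_store`.
#' @export
build_store <- function(release_dirs, overrides = NULL) {
  if (is.null(names(release_dirs)) || any(!nzchar(names(release_dirs)))) {
    stop("release_dirs must be a named vector: label = directory", call. = FALSE)
  }
  labels <- names(release_dirs)
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate release label(s): %s",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")),
         call. = FALSE)
  }
  if (is.character(overrides) && length(overrides) == 1L) {
    overrides <- utils::read.table(overrides, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE, colClasses = "character")
  }
  snaps <- unname(Map(load_release, unname(release_dirs), labels))
  snaps <- snaps[order(vapply(snaps, function(s) ordinal_key(s$release_label), 0))]
  snaps <- canonicalize_series(snaps, overrides)

  manifest <- list(
    releases = vapply(snaps, `[[`, "", "release_label"),
    checksums = lapply(unname(release_dirs), function(d) {
      files <- sort_c(list.files(d, full.names = TRUE))
      as.list(tools::md5sum(files))
    })
  )

  changes <- list()
  states <- list()
  prev_tab <- empty_state_table()
  prev_dead <- character(0)
  for (s in snaps) {
    tab <- state_table(s)
    ev <- diff_states(prev_tab, tab, s$release_label,
                      prev_dead = prev_dead,
                      nxt_dead = snapshot_dead_table(s))
    rows <- events_to_rows(ev)
    changes[[length(changes) + 1L]] <- rows$changes
    states[[length(states) + 1L]] <- rows$states
    prev_tab <- tab
    prev_dead <- vapply(s$dead, `[[`, "", "accession")
  }

  retro <- attr(snaps, "retro_map")
  structure(list(
    changes = do.call(rbind, changes),
    states = do.call(rbind, states),
    releases = data.frame(
      label = vapply(snaps, `[[`, "", "release_label"),
      major = vapply(snaps, function(s) s$ordinal[[1L]], 0),
      minor = vapply(snaps, function(s) s$ordinal[[2L]], 0),
      date = vapply(snaps, function(s) as.character(s$release_date %||% NA_character_), ""),
      stringsAsFactors = FALSE
    ),
    retro = if (is.null(retro)) empty_retro_map() else retro,
    manifest = manifest
  ), class = "event_store")
}

empty_state_table <- function() {
  data.frame(accession = character(0), molecule_type = character(0),
             name = character(0), sequence = character(0),
             species_code = character(0), relations = character(0),
             stringsAsFactors = FALSE)
}

# Retro-assign canonical mature accessions across a sorted snapshot series.
canonicalize_series <- function(snaps, overrides = NULL) {
  has_prov <- vapply(snaps, function(s) {
    any(vapply(s$matures, function(m) isTRUE(m$provisional), TRUE))
  }, TRUE)
  if (!any(has_prov)) return(snaps)
  anchored <- which(!has_prov & vapply(snaps, function(s) length(s$matures) > 0L, TRUE))
  if (!length(anchored)) {
    stop("no anchor release with canonical mature accessions; cannot retro-assign",
         call. = FALSE)
  }
  anchor_i <- anchored[1L]
  pre <- snaps[seq_len(anchor_i - 1L)]
  map <- assign_retro_accessions(pre, snaps[[anchor_i]], overrides)
  for (i in seq_len(anchor_i - 1L)) {
    snaps[[i]] <- apply_retro_map(snaps[[i]], map)
  }
  attr(snaps, "retro_map") <- map
  snaps
}

# Explode one-event-per-accession rows into the persisted one-row-per-type
# CHANGES table plus the STATES table.
events_to_rows <- function(ev) {
  if (!nrow(ev)) {
    return(list(
      changes = data.frame(event_id = character(0), accession = character(0),
                           molecule_type = character(0), change_type = character(0),
                           release_label = character(0), merge_target = character(0),
                           stringsAsFactors = FALSE),
      states = data.frame(event_id = character(0), accession = character(0),
                          name = character(0), sequence = character(0),
                          species_code = character(0), relations = character(0),
                          release_label = character(0), stringsAsFactors = FALSE)))
  }
  types <- strsplit(ev$change_types, ";", fixed = TRUE)
  n_per <- lengths(types)
  changes <- data.frame(
    event_id = rep(ev$event_id, n_per),
    accession = rep(ev$accession, n_per),
    molecule_type = rep(ev$molecule_type, n_per),
    change_type = unlist(types),
    release_label = rep(ev$release_label, n_per),
    merge_target = rep(ev$merge_target, n_per),
    stringsAsFactors = FALSE
  )
  has_state <- !is.na(ev$name)
  states <- data.frame(
    event_id = ev$event_id[has_state],
    accession = ev$accession[has_state],
    name = ev$name[has_state],
    sequence = ev$sequence[has_state],
    species_code = ev$species_code[has_state],
    relations = ev$relations[has_state],
    release_label = ev$release_label[has_state],
    stringsAsFactors = FALSE
  )
  list(changes = changes, states = states)
}

#' @export
print.event_store <- function(x, ...) {
  cat(sprintf("miRBase event store: %d releases (%s..%s), %d change rows, %d states\n",
              nrow(x$releases), x$releases$label[1L],
              x$releases$label[nrow(x$releases)], nrow(x$changes), nrow(x$states)))
  invisible(x)
}

store_check_release <- function(store, release_label) {
  if (!release_label %in% store$releases$label) {
    stop(sprintf("unknown release '%s'; registered: %s", release_label,
                 paste(store$releases$label, collapse = ", ")), call. = FALSE)
  }
}

# Registered labels ordered by numeric ordinal.
store_release_order <- function(store) {
  store$releases$label[order(store$releases$major, store$releases$minor)]
}

latest_release <- function(store) {
  ord <- store_release_order(store)
  ord[length(ord)]
}

#' Reconstruct the annotation state of a release by event replay
#'
#' Replays the store's events in ordinal order from an empty state up to and
#' including `release_label`. The result carries the tracked annotation
#' (accession, molecule type, name, sequence, species code, relations) of
#' every record active in that release; use [state_table()] to compare it with
#' a freshly parsed snapshot.
#'
#' @param store an `event_store`.
#' @param release_label registered release label.
#' @return list with `release_label`, `state` (a [state_table()]-shaped
#'   data.frame) and `dead` (data.frame of accession/forward_to cumulative to
#'   the release), of class `reconstructed_snapshot`.
#' @export
reconstruct_snapshot <- function(store, release_label) {
  store_check_release(store, release_label)
  upto <- ordinal_key(release_label)
  labels <- store_release_order(store)
  labels <- labels[vapply(labels, ordinal_key, 0) <= upto]

  state <- new.env(parent = emptyenv())
  dead <- new.env(parent = emptyenv())
  for (lab in labels) {
    ch <- store$changes[store$changes$release_label == lab, , drop = FALSE]
    st <- store$states[store$states$release_label == lab, , drop = FALSE]
    if (!nrow(ch)) next
    by_acc <- split(seq_len(nrow(ch)), ch$accession)
    for (acc in names(by_acc)) {
      rows <- by_acc[[acc]]
      types <- ch$change_type[rows]
      if ("DELETED" %in% types || "MERGED" %in% types) {
        if (exists(acc, envir = state)) rm(list = acc, envir = state)
        fw <- ch$merge_target[rows][types == "MERGED"]
        assign(acc, if (length(fw)) fw[1L] else NA_character_, envir = dead)
      } else {
        si <- match(ch$event_id[rows[1L]], st$event_id)
        if (is.na(si)) {
          stop(sprintf("store inconsistency: no state for event %s",
                       ch$event_id[rows[1L]]), call. = FALSE)
        }
        assign(acc, list(
          molecule_type = ch$molecule_type[rows[1L]],
          name = st$name[si], sequence = st$sequence[si],
          species_code = st$species_code[si], relations = st$relations[si]
        ), envir = state)
        if (exists(acc, envir = dead)) rm(list = acc, envir = dead)
      }
    }
  }
  accs <- sort_c(ls(envir = state))
  tab <- data.frame(
    accession = accs,
    molecule_type = vapply(accs, function(a) state[[a]]$molecule_type, ""),
    name = vapply(accs, function(a) state[[a]]$name, ""),
    sequence = vapply(accs, function(a) state[[a]]$sequence, ""),
    species_code = vapply(accs, function(a) state[[a]]$species_code, ""),
    relations = vapply(accs, function(a) state[[a]]$relations, ""),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  dacc <- sort_c(ls(envir = dead))
  structure(list(
    release_label = release_label,
    state = tab,
    dead = data.frame(accession = dacc,
                      forward_to = vapply(dacc, function(a) dead[[a]], ""),
                      stringsAsFactors = FALSE)
  ), class = "reconstructed_snapshot")
}

#' @export
print.reconstructed_snapshot <- function(x, ...) {
  cat(sprintf("reconstructed release %s: %d active records, %d dead\n",
              x$release_label, nrow(x$state), nrow(x$dead)))
  invisible(x)
}

#' Dump an event store to portable TSV tables plus a JSON manifest
#'
#' @param store an `event_store`.
#' @param directory output directory.
#' @return `directory`, invisibly.
#' @export
dump_store <- function(store, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) {
    utils::write.table(df, file.path(directory, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  wt(store$changes, "changes.tsv")
  wt(store$states, "states.tsv")
  wt(store$releases, "releases.tsv")
  wt(store$retro, "retro.tsv")
  jsonlite::write_json(store$manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Load an event store dumped by [dump_store()]
#' @param directory directory holding the TSV tables.
#' @return an `event_store`.
#' @export
load_store <- function(directory) {
  rt <- function(f, classes) {
    utils::read.table(file.path(directory, f), sep = "\t", header = TRUE,
                      quote = "", stringsAsFactors = FALSE,
                      colClasses = classes, na.strings = "")
  }
  releases <- rt("releases.tsv", c("character", "numeric", "numeric", "character"))
  structure(list(
    changes = rt("changes.tsv", "character"),
    states = rt("states.tsv", "character"),
    releases = releases,
    retro = rt("retro.tsv", "character"),
    manifest = jsonlite::fromJSON(file.path(directory, "manifest.json"))
  ), class = "event_store")
}
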