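# Release-to-release diff engine.
#
# Identity across releases follows accession numbers, never names: a name that
# disappears from one record and reappears on another yields DELETED + ADDED
# events, not a rename (names have been re-issued for different sequences in
# real miRBase history, e.g. hsa-miR-34b).
#
# Change taxonomy: ADDED, NAME_CHANGE, SEQUENCE_CHANGE, RELATION_CHANGE,
# DELETED, MERGED, RESURRECTED. One event per accession per release
# transition, carrying a set of change types.

CHANGE_TYPES <- c("ADDED", "NAME_CHANGE", "SEQUENCE_CHANGE", "RELATION_CHANGE",
                  "DELETED", "MERGED", "RESURRECTED")

#' Classify the annotation differences between two states of one record
#'
#' Compares the tracked fields of a record's state in two releases: name
#' (case-sensitive), normalized sequence, and the relation set (parent
#' precursors for matures, mature products for precursors).
#'
#' @param old,new rows of a [state_table()] (or lists with `name`, `sequence`,
#'   `relations` fields).
#' @return character vector, a subset of
#'   `{NAME_CHANGE, SEQUENCE_CHANGE, RELATION_CHANGE}`; empty when identical.
#' @export
classify_change <- function(old, new) {
  types <- character(0)
  if (!identical(old$name, new$name)) types <- c(types, "NAME_CHANGE")
  if (!identical(old$sequence, new$sequence)) types <- c(types, "SEQUENCE_CHANGE")
  if (!setequal(split_set(old$relations), split_set(new$relations))) {
    types <- c(types, "RELATION_CHANGE")
  }
  types
}

empty_events <- function() {
  data.frame(event_id = character(0), accession = character(0),
             molecule_type = character(0), release_label = character(0),
             change_types = character(0), merge_target = character(0),
             name = character(0), sequence = character(0),
             species_code = character(0), relations = character(0),
             stringsAsFactors = FALSE)
}

#' Diff two consecutive release snapshots into classified change events
#'
#' For each accession present only in `nxt`, emits `ADDED` — or `RESURRECTED`
#' when the accession appears in `prev`'s cumulative dead list. For each
#' accession present only in `prev`, emits `DELETED`, or `MERGED` with a
#' `merge_target` when `nxt`'s dead file carries a forward pointer. For
#' accessions in both, emits one event whose types come from
#' [classify_change()]; identical records produce no event. Events are ordered
#' by accession (C-locale lexicographic), making output deterministic.
#'
#' @param prev,nxt [release_snapshot()]s with `prev$ordinal < nxt$ordinal`
#'   (canonical accessions already applied).
#' @return data.frame of events with columns `event_id`, `accession`,
#'   `molecule_type`, `release_label`, `change_types` (`;`-joined set),
#'   `merge_target`, and the post-change state (`name`, `sequence`,
#'   `species_code`, `relations`; `NA` for DELETED/MERGED).
#' @export
diff_releases <- function(prev, nxt) {
  if (ordinal_key(prev$release_label) > ordinal_key(nxt$release_label)) {
    stop(sprintf("snapshots out of order: %s !< %s",
                 prev$release_label, nxt$release_label), call. = FALSE)
  }
  diff_states(state_table(prev), state_table(nxt), nxt$release_label,
              prev_dead = vapply(prev$dead, `[[`, "", "accession"),
              nxt_dead = snapshot_dead_table(nxt))
}

snapshot_dead_table <- function(snapshot) {
  data.frame(
    accession = vapply(snapshot$dead, `[[`, "", "accession"),
    forward_to = vapply(snapshot$dead, `[[`, "", "forward_to"),
    stringsAsFactors = FALSE
  )
}

# Core diff over tracked-state tables; release_label is stamped on the events.
diff_states <- function(prev_tab, nxt_tab, release_label,
                        prev_dead = character(0),
                        nxt_dead = data.frame(accession = character(0),
                                              forward_to = character(0))) {
  ev <- empty_events()
  all_acc <- sort_c(union(prev_tab$accession, nxt_tab$accession))
  prev_idx <- match(all_acc, prev_tab$accession)
  nxt_idx <- match(all_acc, nxt_tab$accession)
  for (k in seq_along(all_acc)) {
    acc <- all_acc[k]
    pi <- prev_idx[k]
    ni <- nxt_idx[k]
    if (is.na(pi)) {
      type <- if (acc %in% prev_dead) "RESURRECTED" else "ADDED"
      s <- nxt_tab[ni, ]
      ev[nrow(ev) + 1L, ] <- list(
        event_id(release_label, acc), acc, s$molecule_type, release_label,
        type, NA_character_, s$name, s$sequence, s$species_code, s$relations)
    } else if (is.na(ni)) {
      s <- prev_tab[pi, ]
      fw <- nxt_dead$forward_to[match(acc, nxt_dead$accession)]
      merged <- length(fw) == 1L && !is.na(fw)
      ev[nrow(ev) + 1L, ] <- list(
        event_id(release_label, acc), acc, s$molecule_type, release_label,
        if (merged) "MERGED" else "DELETED",
        if (merged) fw else NA_character_,
        NA_character_, NA_character_, NA_character_, NA_character_)
    } else {
      types <- classify_change(prev_tab[pi, ], nxt_tab[ni, ])
      if (length(types)) {
        s <- nxt_tab[ni, ]
        ev[nrow(ev) + 1L, ] <- list(
          event_id(release_label, acc), acc, s$molecule_type, release_label,
          paste(types, collapse = ";"), NA_character_,
          s$name, s$sequence, s$species_code, s$relations)
      }
    }
  }
  ev
}

event_id <- function(release_label, accession) {
  sprintf("%s:%s", release_label, accession)
}
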