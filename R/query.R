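# User-facing queries over an event store: identifier resolution, per-record
# annotation history, update/reannotation (single and batch) and release
# comparison.

#' Resolve a raw identifier to accessions
#'
#' Auto-detection order: accession pattern (`MI`/`MIMAT`/`PROV` prefix), then
#' sequence pattern (characters in `{A,C,G,U,T,N}` only), then name. Name
#' matches return every accession that ever bore the name (or bore it in
#' `release_context` when given); by default the name comparison is
#' case-insensitive. Sequence matches are exact on the normalized string.
#' An empty result is a value, not an error.
#'
#' @param store an `event_store`.
#' @param raw query string.
#' @param id_type `"auto"`, `"name"`, `"accession"` or `"sequence"`.
#' @param molecule_type `"auto"`, `"mature"` or `"precursor"`.
#' @param release_context optional release label restricting name/sequence
#'   matches to the state of that release.
#' @param ignore_case case-insensitive name matching (default `TRUE`).
#' @return data.frame with columns `accession`, `molecule_type`.
#' @export
resolve_identifier <- function(store, raw, id_type = "auto",
                               molecule_type = "auto", release_context = NULL,
                               ignore_case = TRUE) {
  raw <- trimws(raw)
  if (!nzchar(raw)) stop("empty query", call. = FALSE)
  id_type <- match.arg(id_type, c("auto", "name", "accession", "sequence"))
  molecule_type <- match.arg(molecule_type, c("auto", "mature", "precursor"))
  if (id_type == "auto") {
    id_type <- if (grepl("^(MIMAT|MI|PROV)\\d+$", raw)) "accession"
    else if (grepl("^[ACGUTNacgutn]+$", raw)) "sequence"
    else "name"
  }
  scope <- if (is.null(release_context)) {
    store$states
  } else {
    reconstruct_snapshot(store, release_context)$state
  }
  hits <- switch(id_type,
    accession = scope[scope$accession == raw, c("accession"), drop = FALSE],
    sequence = {
      q <- normalize_rna(raw, "query sequence")
      scope[scope$sequence == q, c("accession"), drop = FALSE]
    },
    name = {
      # exact-case matches win ("mir" vs "miR" distinguishes precursor from
      # mature names); the case-insensitive net is the fallback
      exact <- scope[scope$name == raw, c("accession"), drop = FALSE]
      if (nrow(exact) || !ignore_case) {
        exact
      } else {
        scope[tolower(scope$name) == tolower(raw), c("accession"), drop = FALSE]
      }
    })
  acc <- sort_c(unique(hits$accession))
  out <- data.frame(
    accession = acc,
    molecule_type = ifelse(grepl("^MIMAT", acc), "mature",
                           ifelse(grepl("^MI", acc), "precursor", "mature")),
    stringsAsFactors = FALSE
  )
  # provisional (PROV) accessions are always mature records
  if (molecule_type != "auto") out <- out[out$molecule_type == molecule_type, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# last change row index for an accession, in store release order
accession_events <- function(store, accession) {
  ch <- store$changes[store$changes$accession == accession, , drop = FALSE]
  if (!nrow(ch)) return(ch)
  ch[order(vapply(ch$release_label, ordinal_key, 0), ch$change_type), , drop = FALSE]
}

# chase MERGED forward pointers to the terminal accession; error on cycles
chase_forward <- function(store, accession) {
  seen <- character(0)
  cur <- accession
  repeat {
    if (cur %in% seen) {
      stop(sprintf("cyclic forward pointers: %s",
                   paste(c(seen, cur), collapse = " -> ")), call. = FALSE)
    }
    seen <- c(seen, cur)
    ch <- store$changes
    fw <- ch$merge_target[ch$accession == cur & ch$change_type == "MERGED"]
    fw <- fw[!is.na(fw)]
    if (!length(fw)) return(cur)
    nxt <- fw[length(fw)]
    # the target may itself have been merged later; only follow if currently dead
    status <- accession_status(store, nxt)
    cur <- nxt
    if (status$status == "active") return(cur)
  }
}

# status of an accession at the latest release: active / dead / merged
accession_status <- function(store, accession) {
  ev <- accession_events(store, accession)
  if (!nrow(ev)) return(list(status = "unknown", last_release = NA_character_))
  last_rel <- ev$release_label[nrow(ev)]
  types <- ev$change_type[ev$release_label == last_rel]
  status <- if ("MERGED" %in% types) "merged"
  else if ("DELETED" %in% types) "dead"
  else "active"
  list(status = status, last_release = last_rel,
       merge_target = if (status == "merged") {
         mt <- ev$merge_target[ev$release_label == last_rel & ev$change_type == "MERGED"]
         mt[1L]
       } else NA_character_)
}

# most recent STATES row for an accession (its annotation after the last
# non-removal change)
latest_state <- function(store, accession) {
  st <- store$states[store$states$accession == accession, , drop = FALSE]
  if (!nrow(st)) return(NULL)
  st[which.max(vapply(st$release_label, ordinal_key, 0)), , drop = FALSE]
}

#' Annotation history of a miRNA record
#'
#' Resolves `raw` (name, sequence or accession) and assembles one history per
#' matching accession: the ordered timeline of (release, name, sequence,
#' relations, change types) at every release where an event occurred, plus the
#' record's current status (`active`, `dead`, or `merged-into:<accession>`
#' after transitively chasing forward pointers).
#'
#' @inheritParams resolve_identifier
#' @return list of `annotation_history` objects (empty, with a warning, when
#'   the identifier does not resolve).
#' @export
history_query <- function(store, raw, id_type = "auto", molecule_type = "auto",
                          release_context = NULL, ignore_case = TRUE) {
  m <- resolve_identifier(store, raw, id_type, molecule_type, release_context,
                          ignore_case)
  if (!nrow(m)) {
    warning(sprintf("identifier '%s' does not resolve to any record", raw),
            call. = FALSE)
    return(list())
  }
  lapply(seq_len(nrow(m)), function(i) {
    acc <- m$accession[i]
    ev <- accession_events(store, acc)
    rels <- unique(ev$release_label)
    rels <- rels[order(vapply(rels, ordinal_key, 0))]
    timeline <- do.call(rbind, lapply(rels, function(r) {
      types <- sort_c(ev$change_type[ev$release_label == r])
      eid <- ev$event_id[ev$release_label == r][1L]
      st <- store$states[store$states$event_id == eid, , drop = FALSE]
      data.frame(
        release_label = r,
        name = if (nrow(st)) st$name[1L] else NA_character_,
        sequence = if (nrow(st)) st$sequence[1L] else NA_character_,
        relations = if (nrow(st)) st$relations[1L] else NA_character_,
        change_types = paste(types, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }))
    status <- accession_status(store, acc)
    current_status <- if (status$status == "merged") {
      paste0("merged-into:", chase_forward(store, acc))
    } else status$status
    structure(list(accession = acc, molecule_type = m$molecule_type[i],
                   timeline = timeline, current_status = current_status),
              class = "annotation_history")
  })
}

#' @export
print.annotation_history <- function(x, ...) {
  cat(sprintf("annotation history of %s (%s) — status: %s\n",
              x$accession, x$molecule_type, x$current_status))
  print(x$timeline, row.names = FALSE)
  invisible(x)
}

#' Most up-to-date annotation for a queried identifier
#'
#' Resolves the query, takes the matched record's state at resolution time
#' (the state in `release_context` when given, else the most recent state in
#' which the identifier matched) and compares it with the record's state in
#' the latest release: differing name gives `updated-name`, differing
#' sequence `updated-sequence`, both `updated-both`; a record absent from the
#' latest release is `dead`, or `merged` (forward pointers chased
#' transitively to the terminal accession). Zero matches give `unknown`,
#' several give `ambiguous` (disambiguate with `release_context`).
#'
#' @param store an `event_store`.
#' @param raw query string, or a one-row data.frame as returned by
#'   [read_batch_queries()].
#' @inheritParams resolve_identifier
#' @return one-row data.frame with columns `query`, `id_type`, `status`,
#'   `matched_accession`, `molecule_type`, `latest_name`, `latest_sequence`,
#'   `latest_relations`, `last_change_release`.
#' @export
update_query <- function(store, raw, id_type = "auto", molecule_type = "auto",
                         release_context = NULL, ignore_case = TRUE) {
  if (is.data.frame(raw)) {
    row <- raw[1L, ]
    id_type <- row$id_type %||% "auto"
    molecule_type <- row$molecule_type %||% "auto"
    if (!is.na(row$release_context %||% NA)) release_context <- row$release_context
    raw <- row$raw_query
  }
  res <- function(status, acc = NA_character_, mol = NA_character_,
                  nm = NA_character_, sq = NA_character_, rel = NA_character_,
                  last = NA_character_) {
    data.frame(query = raw, id_type = id_type, status = status,
               matched_accession = acc, molecule_type = mol, latest_name = nm,
               latest_sequence = sq, latest_relations = rel,
               last_change_release = last, stringsAsFactors = FALSE)
  }
  m <- tryCatch(
    resolve_identifier(store, raw, id_type, molecule_type, release_context,
                       ignore_case),
    error = function(e) NULL)
  if (is.null(m) || nrow(m) == 0L) return(res("unknown"))
  if (nrow(m) > 1L) {
    return(res("ambiguous", acc = paste(m$accession, collapse = ";")))
  }
  acc <- m$accession[1L]
  status <- accession_status(store, acc)

  if (status$status %in% c("dead", "merged")) {
    if (status$status == "merged") {
      terminal <- chase_forward(store, acc)
      ls_ <- latest_state(store, terminal)
      return(res("merged", acc = paste0(acc, ">", terminal),
                 mol = m$molecule_type[1L],
                 nm = ls_$name, sq = ls_$sequence, rel = ls_$relations,
                 last = status$last_release))
    }
    return(res("dead", acc = acc, mol = m$molecule_type[1L],
               last = status$last_release))
  }

  latest <- latest_state(store, acc)
  matched <- if (!is.null(release_context)) {
    st <- reconstruct_snapshot(store, release_context)$state
    st[st$accession == acc, , drop = FALSE]
  } else {
    matched_state_at_resolution(store, acc, raw, id_type, ignore_case)
  }
  if (is.null(matched) || !nrow(matched)) matched <- latest
  dn <- !identical(matched$name[1L], latest$name[1L])
  ds <- !identical(matched$sequence[1L], latest$sequence[1L])
  status_str <- if (dn && ds) "updated-both"
  else if (dn) "updated-name"
  else if (ds) "updated-sequence"
  else "current"
  res(status_str, acc = acc, mol = m$molecule_type[1L], nm = latest$name,
      sq = latest$sequence, rel = latest$relations,
      last = latest$release_label)
}

# the most recent stored state in which the raw identifier actually matched
matched_state_at_resolution <- function(store, accession, raw, id_type,
                                        ignore_case) {
  st <- store$states[store$states$accession == accession, , drop = FALSE]
  if (!nrow(st)) return(NULL)
  if (id_type == "auto") {
    id_type <- if (grepl("^(MIMAT|MI|PROV)\\d+$", raw)) "accession"
    else if (grepl("^[ACGUTNacgutn]+$", raw)) "sequence"
    else "name"
  }
  hit <- switch(id_type,
    accession = rep(TRUE, nrow(st)),
    sequence = st$sequence == normalize_rna(raw, "query sequence"),
    name = if (ignore_case) tolower(st$name) == tolower(raw) else st$name == raw)
  st <- st[hit, , drop = FALSE]
  if (!nrow(st)) return(NULL)
  st[which.max(vapply(st$release_label, ordinal_key, 0)), , drop = FALSE]
}

#' Batch reannotation
#'
#' Runs [update_query()] for every row of a batch query table. Unknown or
#' ambiguous rows are flagged in the report, never fatal.
#'
#' @param store an `event_store`.
#' @param rows data.frame from [read_batch_queries()].
#' @return data.frame report, one row per query.
#' @export
batch_update <- function(store, rows) {
  out <- lapply(seq_len(nrow(rows)), function(i) update_query(store, rows[i, ]))
  do.call(rbind, out)
}

#' Compare two releases
#'
#' Computes, from reconstructed snapshots (never by summing events, so gaps in
#' the ingested series are handled correctly), which records were added,
#' removed (split into deleted and merged using the dead-entry forward
#' pointers of `release_b`), changed (name, sequence and/or relations — a
#' record may appear in several changed sets; the summary `changed` bucket is
#' their union) or remained unchanged between `release_a` and `release_b`.
#' Direction is respected: `release_a` may be later than `release_b`.
#'
#' @param store an `event_store`.
#' @param release_a,release_b registered release labels.
#' @param species optional species code filter (e.g. `"mmu"`).
#' @param molecule_type `"mature"`, `"precursor"` or `"both"`.
#' @return an object of class `comparison_report` with the sets (`added`,
#'   `removed_deleted`, `removed_merged`, `name_changed`, `sequence_changed`,
#'   `relation_changed`, `unchanged`) and `summary` counts.
#' @export
compare_releases <- function(store, release_a, release_b, species = NULL,
                             molecule_type = c("mature", "precursor", "both")) {
  molecule_type <- match.arg(molecule_type)
  store_check_release(store, release_a)
  store_check_release(store, release_b)
  ra <- reconstruct_snapshot(store, release_a)
  rb <- reconstruct_snapshot(store, release_b)
  filt <- function(tab) {
    if (molecule_type != "both") tab <- tab[tab$molecule_type == molecule_type, , drop = FALSE]
    if (!is.null(species)) tab <- tab[tab$species_code == species, , drop = FALSE]
    tab
  }
  ta <- filt(ra$state)
  tb <- filt(rb$state)
  only_b <- setdiff(tb$accession, ta$accession)
  only_a <- setdiff(ta$accession, tb$accession)
  both <- intersect(ta$accession, tb$accession)

  dead_b <- rb$dead
  fw <- dead_b$forward_to[match(only_a, dead_b$accession)]
  removed_merged <- only_a[!is.na(fw)]
  removed_deleted <- setdiff(only_a, removed_merged)

  ia <- match(both, ta$accession)
  ib <- match(both, tb$accession)
  name_changed <- both[ta$name[ia] != tb$name[ib]]
  sequence_changed <- both[ta$sequence[ia] != tb$sequence[ib]]
  rel_diff <- vapply(seq_along(both), function(k) {
    !setequal(split_set(ta$relations[ia[k]]), split_set(tb$relations[ib[k]]))
  }, TRUE)
  relation_changed <- both[rel_diff]
  changed <- union(union(name_changed, sequence_changed), relation_changed)
  unchanged <- setdiff(both, changed)

  sets <- list(added = sort_c(only_b),
               removed_deleted = sort_c(removed_deleted),
               removed_merged = sort_c(removed_merged),
               name_changed = sort_c(name_changed),
               sequence_changed = sort_c(sequence_changed),
               relation_changed = sort_c(relation_changed),
               unchanged = sort_c(unchanged))
  structure(c(list(release_a = release_a, release_b = release_b,
                   species = species %||% "all", molecule_type = molecule_type),
              sets,
              list(summary = c(
                added = length(sets$added),
                removed = length(sets$removed_deleted) + length(sets$removed_merged),
                removed_deleted = length(sets$removed_deleted),
                removed_merged = length(sets$removed_merged),
                changed = length(changed),
                name_changed = length(sets$name_changed),
                sequence_changed = length(sets$sequence_changed),
                relation_changed = length(sets$relation_changed),
                unchanged = length(sets$unchanged)))),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("miRBase release comparison %s -> %s (%s, %s miRNAs)\n",
              x$release_a, x$release_b, x$species, x$molecule_type))
  s <- x$summary
  cat(sprintf("  added: %d  removed: %d (deleted %d, merged %d)\n",
              s[["added"]], s[["removed"]], s[["removed_deleted"]],
              s[["removed_merged"]]))
  cat(sprintf("  changed: %d (name %d, sequence %d, relations %d)  unchanged: %d\n",
              s[["changed"]], s[["name_changed"]], s[["sequence_changed"]],
              s[["relation_changed"]], s[["unchanged"]]))
  invisible(x)
}
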