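# Retro-assignment of canonical accessions to pre-accession mature records.
#
# Mature miRNA accessions only exist from miRBase release 6.0 onwards; earlier
# mature records are identified by (species, name, sequence) and must be
# reconciled to later accessions before releases can be diffed by accession.
# Matching walks backwards from the anchor release, so assignments propagate
# through chains of early releases.

#' Assign canonical accessions to pre-accession mature records
#'
#' Walks backwards from the anchor (the earliest release whose matures all
#' carry canonical accessions). Each unaccessioned mature is matched against
#' the already-canonicalized next-later release by a rule cascade:
#' \enumerate{
#'   \item `rule:name` — exact species + name match;
#'   \item `rule:sequence` — exact sequence match within the species;
#'   \item `rule:overlap` — maximal sequence overlap (one sequence contained in
#'     the other, or sharing >= 16 contiguous nt), ties broken by name edit
#'     distance then lexicographic name.
#' }
#' Explicit overrides take absolute precedence. Records with no match receive
#' fresh provisional accessions (`PROV` namespace), guaranteeing totality; the
#' provisional id is content-derived and therefore stable across rebuilds.
#' Assignments are injective within a release: a rule that would re-use an
#' accession already taken in the same release falls through to the next rule.
#'
#' @param snapshots_pre list of [release_snapshot()]s predating mature
#'   accessions, in increasing ordinal order.
#' @param anchor the first accessioned [release_snapshot()].
#' @param overrides optional data.frame with columns `release`, `species_code`,
#'   `name`, `sequence`, `accession` (the overrides TSV layout). An override
#'   naming an accession unknown to the anchor era is an error.
#' @return data.frame map with columns `release_label`, `species_code`, `name`,
#'   `sequence`, `accession`, `provenance`
#'   (`rule:name`/`rule:sequence`/`rule:overlap`/`override`/`provisional`).
#' @export
assign_retro_accessions <- function(snapshots_pre, anchor, overrides = NULL) {
  if (length(snapshots_pre) == 0L) return(empty_retro_map())
  ord <- order(vapply(snapshots_pre, function(s) ordinal_key(s$release_label), 0))
  snapshots_pre <- snapshots_pre[ord]

  anchor_accessions <- c(
    names(anchor$matures),
    vapply(anchor$dead, `[[`, "", "accession")
  )
  if (!is.null(overrides) && nrow(overrides)) {
    unknown <- setdiff(overrides$accession, anchor_accessions)
    if (length(unknown)) {
      stop(sprintf("override names accession(s) unknown to the anchor release: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }

  map <- empty_retro_map()
  # reference = canonical records of the next-later release (anchor first)
  reference <- mature_key_table(anchor)
  for (i in rev(seq_along(snapshots_pre))) {
    snap <- snapshots_pre[[i]]
    rel <- snap$release_label
    recs <- snap$matures[order_c(vapply(snap$matures, `[[`, "", "name"),
                                 vapply(snap$matures, `[[`, "", "sequence"))]
    taken <- character(0)
    assigned <- list()
    for (m in recs) {
      entry <- retro_match_one(m, rel, reference, overrides, taken)
      taken <- c(taken, entry$accession)
      map[nrow(map) + 1L, ] <- list(rel, m$species_code, m$name, m$sequence,
                                    entry$accession, entry$provenance)
      assigned[[length(assigned) + 1L]] <-
        list(accession = entry$accession, name = m$name,
             species_code = m$species_code, sequence = m$sequence)
    }
    # this release, now canonicalized, becomes the reference for the next-older
    # one; the anchor remains a fallback so records spanning a gap still match
    canon <- do.call(rbind, lapply(assigned, function(a) {
      data.frame(accession = a$accession, name = a$name,
                 species_code = a$species_code, sequence = a$sequence,
                 stringsAsFactors = FALSE)
    }))
    reference <- rbind(canon, mature_key_table(anchor))
    reference <- reference[!duplicated(reference$accession), , drop = FALSE]
  }
  map
}

empty_retro_map <- function() {
  data.frame(release_label = character(0), species_code = character(0),
             name = character(0), sequence = character(0),
             accession = character(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

mature_key_table <- function(snapshot) {
  m <- snapshot$matures
  data.frame(
    accession = vapply(m, `[[`, "", "accession"),
    name = vapply(m, `[[`, "", "name"),
    species_code = vapply(m, `[[`, "", "species_code"),
    sequence = vapply(m, `[[`, "", "sequence"),
    stringsAsFactors = FALSE
  )
}

retro_match_one <- function(m, release_label, reference, overrides, taken) {
  # overrides take absolute precedence
  if (!is.null(overrides) && nrow(overrides)) {
    hit <- overrides$release == release_label &
      overrides$species_code == m$species_code &
      overrides$name == m$name & overrides$sequence == m$sequence
    if (any(hit)) {
      return(list(accession = overrides$accession[which(hit)[1L]],
                  provenance = "override"))
    }
  }
  free <- reference[!(reference$accession %in% taken), , drop = FALSE]
  sp <- free[free$species_code == m$species_code, , drop = FALSE]
  # rule 1: exact species + name
  hit <- which(sp$name == m$name)
  if (length(hit)) {
    return(list(accession = sp$accession[hit[1L]], provenance = "rule:name"))
  }
  # rule 2: exact sequence within species
  hit <- which(sp$sequence == m$sequence)
  if (length(hit)) {
    return(list(accession = sp$accession[hit[1L]], provenance = "rule:sequence"))
  }
  # rule 3: maximal contiguous overlap (containment or >= 16 shared nt)
  if (nrow(sp)) {
    ov <- vapply(sp$sequence, function(s) longest_common_substring(m$sequence, s), 0L)
    best <- max(ov)
    if (best >= 16L || any(ov == nchar(m$sequence)) ||
        any(ov == nchar(sp$sequence) & ov > 0L)) {
      cand <- which(ov == best)
      if (length(cand) > 1L) {
        d <- utils::adist(m$name, sp$name[cand])[1L, ]
        cand <- cand[d == min(d)]
        cand <- cand[order_c(sp$name[cand])]
      }
      return(list(accession = sp$accession[cand[1L]], provenance = "rule:overlap"))
    }
  }
  list(accession = provisional_accession(m$species_code, m$name, m$sequence),
       provenance = "provisional")
}

# length of the longest common contiguous substring (dynamic programme;
# sequences are ~22 nt so the quadratic cost is negligible)
longest_common_substring <- function(a, b) {
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  best <- 0L
  prev <- integer(length(bv))
  for (i in seq_along(av)) {
    cur <- integer(length(bv))
    match_b <- which(bv == av[i])
    for (j in match_b) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best) best <- cur[j]
    }
    prev <- cur
  }
  best
}

#' Apply a retro-accession map to a snapshot
#'
#' Replaces provisional mature accessions with the canonical accessions from
#' `map`, in both the mature records and the FT features that reference them.
#'
#' @param snapshot a [release_snapshot()].
#' @param map data.frame from [assign_retro_accessions()].
#' @return the rewritten [release_snapshot()].
#' @export
apply_retro_map <- function(snapshot, map) {
  rel <- map[map$release_label == snapshot$release_label, , drop = FALSE]
  if (!nrow(rel)) return(snapshot)
  lookup <- function(m) {
    hit <- rel$species_code == m$species_code & rel$name == m$name &
      rel$sequence == m$sequence
    if (any(hit)) rel$accession[which(hit)[1L]] else m$accession
  }
  old_new <- c()
  matures <- lapply(snapshot$matures, function(m) {
    if (!isTRUE(m$provisional)) return(m)
    new_acc <- lookup(m)
    old_new[[m$accession]] <<- new_acc
    mature_record(new_acc, m$name, m$sequence, m$parent_precursors,
                  provisional = startsWith(new_acc, "PROV"))
  })
  precursors <- lapply(snapshot$precursors, function(p) {
    fa <- p$mature_features$mature_accession
    hit <- !is.na(fa) & fa %in% names(old_new)
    if (any(hit)) {
      p$mature_features$mature_accession[hit] <- unlist(old_new[fa[hit]])
    }
    p
  })
  release_snapshot(snapshot$release_label, precursors, matures, snapshot$dead,
                   release_date = snapshot$release_date, validate = FALSE)
}
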