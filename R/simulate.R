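# Synthetic miRBase release-series generator.
#
# Emits a multi-release series in the exact miRNA.dat / mature.fa / miRNA.dead
# dialects together with a machine-readable ground-truth change log, so the
# parser, diff engine, store and queries are all testable offline. Precursor
# sequences are i.i.d. uniform over {A,C,G,U} at 60-120 nt with mature
# features of 20-24 nt; no hairpin realism is attempted (annotation tracking,
# not RNA folding, is what the series exercises).

#' Parameters for a simulated release series
#'
#' Per-transition rates are per-record probabilities; operations are mutually
#' exclusive per precursor within one transition (a record can still
#' accumulate different changes across transitions).
#'
#' @param n_species number of synthetic species.
#' @param n_initial_precursors precursors in the first release.
#' @param matures_per_precursor 1 or 2 mature products per precursor (2 gives
#'   -5p/-3p arm pairs).
#' @param n_releases number of releases (>= 1).
#' @param p_add per-precursor probability that a transition spawns a new record.
#' @param p_delete,p_merge,p_rename,p_seqchange,p_relink,p_resurrect
#'   per-record probabilities of the corresponding annotation change.
#'   Sequence changes are an end-shift of 1-2 nt or one point substitution,
#'   the isomiR-style edits that dominate real mature-sequence revisions.
#' @param p_seed_region_hit probability that a sequence change alters seed
#'   positions 2-8.
#' @param rng_seed integer seed; identical params + seed give byte-identical
#'   output files.
#' @param accession_epoch release index before which matures are emitted
#'   without accessions (exercises retro-assignment); 1 means all releases
#'   carry accessions.
#' @param reissue_names when `TRUE`, additions may re-use a retired name for a
#'   new accession (the name-reuse hazard seen in real nomenclature history).
#' @return a validated `simulation_params` list.
#' @export
simulation_params <- function(n_species = 3, n_initial_precursors = 30,
                              matures_per_precursor = 2, n_releases = 6,
                              p_add = 0.05, p_delete = 0.02, p_merge = 0.02,
                              p_rename = 0.06, p_seqchange = 0.06,
                              p_relink = 0.02, p_resurrect = 0.05,
                              p_seed_region_hit = 0.5, rng_seed = 42,
                              accession_epoch = 1, reissue_names = FALSE) {
  rates <- c(p_add = p_add, p_delete = p_delete, p_merge = p_merge,
             p_rename = p_rename, p_seqchange = p_seqchange,
             p_relink = p_relink, p_resurrect = p_resurrect,
             p_seed_region_hit = p_seed_region_hit)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]", call. = FALSE)
  if (n_releases < 1) stop("n_releases must be >= 1", call. = FALSE)
  if (!matures_per_precursor %in% c(1, 2)) {
    stop("matures_per_precursor must be 1 or 2", call. = FALSE)
  }
  if (sum(rates[c("p_delete", "p_merge", "p_rename", "p_seqchange", "p_relink")]) > 1) {
    stop("per-record operation rates must sum to <= 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "simulation_params")
}

species_code_for <- function(i) {
  paste0("s", letters[(i - 1L) %/% 26L + 1L], letters[(i - 1L) %% 26L + 1L])
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

pick1 <- function(x) if (length(x) <= 1L) x else x[sample.int(length(x), 1L)]

#' Mutate a miRNA name following the nomenclature conventions
#'
#' Modes: `add-arm-suffix` appends `-5p`/`-3p`; `add-family-letter` inserts a
#' homolog family letter after the number (before any locus/arm suffix);
#' `add-locus-number` appends a paralog locus number; `star-to-arm` rewrites a
#' legacy `*` (minor strand) name to arm-suffix style.
#'
#' @param name a convention-conforming miRNA name, e.g. `"hsa-miR-378"`.
#' @param mode one of the four modes above.
#' @param arm `"5p"` or `"3p"`, used by `add-arm-suffix` and `star-to-arm`.
#' @param letter family letter for `add-family-letter`.
#' @param locus locus number for `add-locus-number`.
#' @return the mutated name.
#' @export
#' @examples
#' name_mutator("hsa-miR-378", "add-arm-suffix", arm = "3p")
#' name_mutator(name_mutator("hsa-miR-378", "add-family-letter"), "add-arm-suffix",
#'              arm = "3p")  # "hsa-miR-378a-3p"
name_mutator <- function(name, mode = c("add-arm-suffix", "add-family-letter",
                                        "add-locus-number", "star-to-arm"),
                         arm = "3p", letter = "a", locus = 1L) {
  mode <- match.arg(mode)
  p <- parse_mirna_name(name)
  if (is.null(p)) stop(sprintf("name '%s' does not follow the convention grammar", name),
                       call. = FALSE)
  switch(mode,
    "add-arm-suffix" = {
      if (nzchar(p$arm)) stop(sprintf("'%s' already carries an arm suffix", name),
                              call. = FALSE)
      p$arm <- arm
      p$star <- ""
    },
    "add-family-letter" = {
      p$letter <- letter
    },
    "add-locus-number" = {
      p$locus <- as.character(locus)
    },
    "star-to-arm" = {
      if (!nzchar(p$star)) stop(sprintf("'%s' is not a star name", name), call. = FALSE)
      p$star <- ""
      p$arm <- arm
    })
  unparse_mirna_name(p)
}

# grammar: <species 3-4 letters>-<mir|miR|let|lin>-<number><letter?>(-<locus>)?(-<5p|3p>)?<*?>
parse_mirna_name <- function(name) {
  m <- regexec("^([a-z]{3,4})-(mir|miR|let|lin)-(\\d+)([a-z]?)(?:-(\\d+))?(?:-(5p|3p))?(\\*?)$",
               name)
  g <- regmatches(name, m)[[1]]
  if (!length(g)) return(NULL)
  list(species = g[2L], stem = g[3L], number = g[4L], letter = g[5L],
       locus = g[6L], arm = g[7L], star = g[8L])
}

unparse_mirna_name <- function(p) {
  paste0(p$species, "-", p$stem, "-", p$number, p$letter,
         if (nzchar(p$locus)) paste0("-", p$locus) else "",
         if (nzchar(p$arm)) paste0("-", p$arm) else "",
         p$star)
}

#' Check a name against the nomenclature grammar
#' @param name candidate string.
#' @return `TRUE` when the name parses under the convention grammar.
#' @export
mirna_name_valid <- function(name) !is.null(parse_mirna_name(name))

# precursor name "spp-mir-378a-2" -> mature base "spp-miR-378a-2"
prec_to_mat_base <- function(prec_name) sub("-mir-", "-miR-", prec_name, fixed = TRUE)

mat_name_of <- function(prec_name, arm) {
  base <- prec_to_mat_base(prec_name)
  if (nzchar(arm)) paste0(base, "-", arm) else base
}

#' Simulate a multi-release miRBase series with a ground-truth change log
#'
#' Writes one directory per release under `out_dir` (each holding miRNA.dat,
#' mature.fa and miRNA.dead in the real dialects) plus `ground_truth.tsv` and
#' `ground_truth.json`. The log records every injected change with the same
#' taxonomy and canonical ordering the diff engine emits, so on
#' non-adversarial parameters `build_store()` output matches it exactly.
#'
#' @param params a [simulation_params()] object.
#' @param out_dir output directory.
#' @return list with `dirs` (named `label = directory`), `log` (the
#'   ground-truth data.frame) and `params`.
#' @export
simulate_release_series <- function(params, out_dir) {
  stopifnot(inherits(params, "simulation_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(params$rng_seed, simulate_series_impl(params, out_dir))
}

simulate_series_impl <- function(params, out_dir) {
  db <- new.env(parent = emptyenv())
  db$prec <- list()       # accession -> precursor state
  db$mat <- list()        # accession -> mature state (accession, name, arm, parents)
  db$dead <- list()       # accession -> dead entry fields
  db$graveyard <- list()  # precursor accession -> resurrectable copy
  db$retired_names <- character(0)
  db$mi_counter <- 0L
  db$mimat_counter <- 0L
  db$species_counter <- stats::setNames(rep(0L, params$n_species),
                                        vapply(seq_len(params$n_species),
                                               species_code_for, ""))
  db$log <- list()

  labels <- sprintf("%d.0", seq_len(params$n_releases))
  dirs <- character(0)

  for (r in seq_len(params$n_releases)) {
    lab <- labels[r]
    if (r == 1L) {
      for (i in seq_len(params$n_initial_precursors)) add_precursor(db, params, lab)
    } else {
      run_transition(db, params, lab)
    }
    if (length(db$prec) == 0L && r < params$n_releases) {
      stop(sprintf("simulated database empty after release %s; lower the removal rates",
                   lab), call. = FALSE)
    }
    snap <- db_to_snapshot(db, lab)
    dir <- file.path(out_dir, paste0("rel_", lab))
    write_release(snap, dir, mature_accessions = r >= params$accession_epoch)
    dirs[lab] <- dir
  }

  log <- do.call(rbind, db$log)
  rownames(log) <- NULL
  utils::write.table(log, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(log, file.path(out_dir, "ground_truth.json"),
                       dataframe = "rows", na = "null", digits = NA)
  list(dirs = dirs, log = log, params = params)
}

log_event <- function(db, release_label, accession, molecule_type, types,
                      old_name = NA, new_name = NA, old_seq = NA, new_seq = NA,
                      merge_target = NA) {
  types <- intersect(CHANGE_TYPES, types)  # canonical taxonomy order
  db$log[[length(db$log) + 1L]] <- data.frame(
    release_label = release_label, accession = accession,
    molecule_type = molecule_type, change_types = paste(types, collapse = ";"),
    old_name = as.character(old_name), new_name = as.character(new_name),
    old_sequence = as.character(old_seq), new_sequence = as.character(new_seq),
    merge_target = as.character(merge_target), stringsAsFactors = FALSE)
}

next_mi <- function(db) {
  db$mi_counter <- db$mi_counter + 1L
  sprintf("MI%07d", db$mi_counter)
}
next_mimat <- function(db) {
  db$mimat_counter <- db$mimat_counter + 1L
  sprintf("MIMAT%07d", db$mimat_counter)
}

# Create one precursor with its mature(s) and log ADDED events.
add_precursor <- function(db, params, release_label, reuse_name = NULL) {
  sp <- pick1(names(db$species_counter))
  if (is.null(reuse_name)) {
    db$species_counter[[sp]] <- db$species_counter[[sp]] + 1L
    pname <- sprintf("%s-mir-%d", sp, db$species_counter[[sp]])
  } else {
    pname <- reuse_name
    sp <- species_of(pname)
  }
  n_arms <- params$matures_per_precursor
  len <- sample(60:120, 1L)
  seq <- random_rna(len)
  acc <- next_mi(db)
  arms <- if (n_arms == 2L) c("5p", "3p") else ""
  feats <- empty_features()
  mats <- list()
  for (k in seq_len(n_arms)) {
    L <- sample(20:24, 1L)
    if (n_arms == 2L && k == 1L) {
      s <- sample(2:5, 1L)
    } else if (n_arms == 2L) {
      s <- len - L - sample(1:4, 1L)
    } else {
      s <- sample(2:(len - L), 1L)
    }
    e <- s + L - 1L
    macc <- next_mimat(db)
    mname <- mat_name_of(pname, arms[k])
    feats[nrow(feats) + 1L, ] <- list(macc, mname, s, e, "experimental")
    mats[[macc]] <- list(accession = macc, name = mname, arm = arms[k],
                         parents = acc)
  }
  db$prec[[acc]] <- list(accession = acc, name = pname, species_code = sp,
                         species_name = paste0("Simulatus ", sp, "ensis"),
                         sequence = seq, features = feats)
  log_event(db, release_label, acc, "precursor", "ADDED", new_name = pname,
            new_seq = seq)
  for (macc in names(mats)) {
    db$mat[[macc]] <- mats[[macc]]
    log_event(db, release_label, macc, "mature", "ADDED",
              new_name = mats[[macc]]$name,
              new_seq = mature_sequence(db, macc))
  }
  acc
}

mature_sequence <- function(db, macc) {
  m <- db$mat[[macc]]
  p <- db$prec[[m$parents[1L]]]
  i <- match(macc, p$features$mature_accession)
  substr(p$sequence, p$features$start[i], p$features$end[i])
}

matures_of <- function(db, pacc) {
  db$prec[[pacc]]$features$mature_accession
}

run_transition <- function(db, params, lab) {
  active <- sort_c(names(db$prec))
  # resurrection candidates are records dead in an earlier release, not ones
  # deleted within this very transition (that would be a net no-op)
  grave0 <- sort_c(names(db$graveyard))
  n_active <- length(active)
  u <- stats::runif(n_active)
  cu <- cumsum(c(params$p_delete, params$p_merge, params$p_relink,
                 params$p_rename, params$p_seqchange))
  op <- ifelse(u < cu[1L], "delete",
        ifelse(u < cu[2L], "merge",
        ifelse(u < cu[3L], "relink",
        ifelse(u < cu[4L], "rename",
        ifelse(u < cu[5L], "seqchange", "none")))))
  pool_none <- active[op == "none"]

  for (acc in active[op == "merge"]) {
    targets <- setdiff(pool_none, acc)
    targets <- targets[vapply(targets, function(t) length(matures_of(db, t)) > 0L, TRUE)]
    if (!length(targets)) next
    do_merge(db, lab, acc, pick1(targets))
  }
  for (acc in active[op == "delete"]) do_delete(db, lab, acc)
  for (acc in active[op == "relink"]) {
    # relinks stay within the species: a mature's name prefix is its species
    sp <- db$prec[[acc]]$species_code
    targets <- setdiff(pool_none, acc)
    targets <- targets[vapply(targets, function(t) db$prec[[t]]$species_code == sp, TRUE)]
    if (!length(targets) || !length(matures_of(db, acc))) next
    tgt <- pick1(targets)
    pool_none <- setdiff(pool_none, tgt)  # target mutates; use it once
    do_relink(db, lab, acc, tgt)
  }
  for (acc in active[op == "rename"]) do_rename(db, lab, acc)
  for (acc in active[op == "seqchange"]) do_seqchange(db, params, lab, acc)

  n_add <- stats::rbinom(1L, n_active, params$p_add)
  for (i in seq_len(n_add)) {
    reuse <- NULL
    if (params$reissue_names && length(db$retired_names)) {
      reuse <- db$retired_names[1L]
      db$retired_names <- db$retired_names[-1L]
    }
    add_precursor(db, params, lab, reuse_name = reuse)
  }

  for (pacc in grave0) {
    if (is.null(db$graveyard[[pacc]])) next
    if (stats::runif(1L) < params$p_resurrect) do_resurrect(db, lab, pacc)
  }
}

do_delete <- function(db, lab, pacc) {
  p <- db$prec[[pacc]]
  mats <- matures_of(db, pacc)
  db$graveyard[[pacc]] <- list(prec = p, matures = db$mat[mats])
  for (macc in mats) {
    db$dead[[macc]] <- list(accession = macc, last_name = db$mat[[macc]]$name,
                            forward_to = NA_character_)
    log_event(db, lab, macc, "mature", "DELETED", old_name = db$mat[[macc]]$name,
              old_seq = mature_sequence(db, macc))
    db$mat[[macc]] <- NULL
  }
  db$dead[[pacc]] <- list(accession = pacc, last_name = p$name,
                          forward_to = NA_character_)
  log_event(db, lab, pacc, "precursor", "DELETED", old_name = p$name,
            old_seq = p$sequence)
  db$prec[[pacc]] <- NULL
}

do_merge <- function(db, lab, pacc, target) {
  p <- db$prec[[pacc]]
  tgt_mats <- matures_of(db, target)
  for (macc in matures_of(db, pacc)) {
    mtgt <- tgt_mats[1L]
    db$dead[[macc]] <- list(accession = macc, last_name = db$mat[[macc]]$name,
                            forward_to = mtgt)
    log_event(db, lab, macc, "mature", "MERGED", old_name = db$mat[[macc]]$name,
              old_seq = mature_sequence(db, macc), merge_target = mtgt)
    db$mat[[macc]] <- NULL
  }
  db$dead[[pacc]] <- list(accession = pacc, last_name = p$name, forward_to = target)
  db$retired_names <- c(db$retired_names, p$name)
  log_event(db, lab, pacc, "precursor", "MERGED", old_name = p$name,
            old_seq = p$sequence, merge_target = target)
  db$prec[[pacc]] <- NULL
}

do_rename <- function(db, lab, pacc) {
  p <- db$prec[[pacc]]
  old <- p$name
  parsed <- parse_mirna_name(old)
  new <- if (!nzchar(parsed$letter)) {
    name_mutator(old, "add-family-letter", letter = pick1(letters[1:4]))
  } else if (!nzchar(parsed$locus)) {
    name_mutator(old, "add-locus-number", locus = sample(1:3, 1L))
  } else {
    return(invisible())  # name already fully decorated; leave it
  }
  db$prec[[pacc]]$name <- new
  log_event(db, lab, pacc, "precursor", "NAME_CHANGE", old_name = old,
            new_name = new, old_seq = p$sequence, new_seq = p$sequence)
  for (macc in matures_of(db, pacc)) {
    m <- db$mat[[macc]]
    mold <- m$name
    # only matures whose name derives from this precursor follow the rename;
    # relinked-in matures keep their own names (avoids name collisions)
    if (mold != mat_name_of(old, m$arm)) next
    mnew <- mat_name_of(new, m$arm)
    db$mat[[macc]]$name <- mnew
    i <- match(macc, db$prec[[pacc]]$features$mature_accession)
    db$prec[[pacc]]$features$product[i] <- mnew
    sq <- mature_sequence(db, macc)
    log_event(db, lab, macc, "mature", "NAME_CHANGE", old_name = mold,
              new_name = mnew, old_seq = sq, new_seq = sq)
  }
}

do_seqchange <- function(db, params, lab, pacc) {
  mats <- matures_of(db, pacc)
  if (!length(mats)) return(invisible())
  macc <- pick1(mats)
  p <- db$prec[[pacc]]
  i <- match(macc, p$features$mature_accession)
  s <- p$features$start[i]
  e <- p$features$end[i]
  old_mat <- substr(p$sequence, s, e)
  seed_hit <- stats::runif(1L) < params$p_seed_region_hit
  other <- setdiff(seq_len(nrow(p$features)), i)

  shift_ok <- function(ns, ne) {
    if (ns < 1L || ne > nchar(p$sequence) || ns >= ne) return(FALSE)
    for (j in other) {
      if (ns <= p$features$end[j] && p$features$start[j] <= ne) return(FALSE)
    }
    TRUE
  }

  mode <- if (stats::runif(1L) < 0.5) "shift" else "subst"
  done <- FALSE
  if (mode == "shift") {
    d <- sample(1:2, 1L) * pick1(c(-1L, 1L))
    # a 5' end shift reframes the seed; a 3' shift leaves positions 2-8 intact
    if (seed_hit) {
      if (shift_ok(s + d, e)) {
        db$prec[[pacc]]$features$start[i] <- s + d
        done <- TRUE
      }
    } else {
      if (shift_ok(s, e + d)) {
        db$prec[[pacc]]$features$end[i] <- e + d
        done <- TRUE
      }
    }
    if (done) {
      new_mat <- mature_sequence(db, macc)
      if (new_mat == old_mat) {
        # degenerate repeat made the shift a no-op; revert, fall back to a
        # substitution so the injected event always corresponds to a real change
        db$prec[[pacc]]$features$start[i] <- s
        db$prec[[pacc]]$features$end[i] <- e
      } else {
        log_event(db, lab, macc, "mature", "SEQUENCE_CHANGE",
                  old_name = db$mat[[macc]]$name, new_name = db$mat[[macc]]$name,
                  old_seq = old_mat, new_seq = new_mat)
        return(invisible())
      }
    }
  }
  # point substitution (also the fallback when no shift fits):
  # changes both the mature and the precursor sequence
  L <- e - s + 1L
  pos <- if (seed_hit) sample(2:min(8L, L), 1L) else sample(seq_len(L), 1L)
  g <- s + pos - 1L
  old_base <- substr(p$sequence, g, g)
  new_base <- pick1(setdiff(c("A", "C", "G", "U"), old_base))
  old_prec <- p$sequence
  new_prec <- paste0(substr(old_prec, 1L, g - 1L), new_base,
                     substr(old_prec, g + 1L, nchar(old_prec)))
  db$prec[[pacc]]$sequence <- new_prec
  new_mat <- mature_sequence(db, macc)
  log_event(db, lab, pacc, "precursor", "SEQUENCE_CHANGE",
            old_name = p$name, new_name = p$name,
            old_seq = old_prec, new_seq = new_prec)
  log_event(db, lab, macc, "mature", "SEQUENCE_CHANGE",
            old_name = db$mat[[macc]]$name, new_name = db$mat[[macc]]$name,
            old_seq = old_mat, new_seq = new_mat)
}

# Move one mature of `pacc` to `target` by appending its sequence to the
# target precursor (the simplest embedding that keeps every invariant).
do_relink <- function(db, lab, pacc, target) {
  mats <- matures_of(db, pacc)
  macc <- mats[1L]
  mseq <- mature_sequence(db, macc)
  p <- db$prec[[pacc]]
  q <- db$prec[[target]]
  i <- match(macc, p$features$mature_accession)

  db$prec[[pacc]]$features <- p$features[-i, , drop = FALSE]
  old_q_seq <- q$sequence
  new_q_seq <- paste0(old_q_seq, mseq)
  db$prec[[target]]$sequence <- new_q_seq
  db$prec[[target]]$features[nrow(q$features) + 1L, ] <-
    list(macc, db$mat[[macc]]$name, nchar(old_q_seq) + 1L, nchar(new_q_seq),
         "experimental")
  db$mat[[macc]]$parents <- target

  log_event(db, lab, macc, "mature", "RELATION_CHANGE",
            old_name = db$mat[[macc]]$name, new_name = db$mat[[macc]]$name,
            old_seq = mseq, new_seq = mseq)
  log_event(db, lab, pacc, "precursor", "RELATION_CHANGE",
            old_name = p$name, new_name = p$name,
            old_seq = p$sequence, new_seq = p$sequence)
  log_event(db, lab, target, "precursor", c("SEQUENCE_CHANGE", "RELATION_CHANGE"),
            old_name = q$name, new_name = q$name,
            old_seq = old_q_seq, new_seq = new_q_seq)
}

do_resurrect <- function(db, lab, pacc) {
  entry <- db$graveyard[[pacc]]
  # only restore if nothing conflicting was added meanwhile
  if (!is.null(db$prec[[pacc]])) return(invisible())
  active_names <- c(vapply(db$prec, `[[`, "", "name"),
                    vapply(db$mat, `[[`, "", "name"))
  wanted <- c(entry$prec$name, vapply(entry$matures, `[[`, "", "name"))
  if (any(wanted %in% active_names)) return(invisible())
  db$prec[[pacc]] <- entry$prec
  db$dead[[pacc]] <- NULL
  log_event(db, lab, pacc, "precursor", "RESURRECTED",
            new_name = entry$prec$name, new_seq = entry$prec$sequence)
  for (macc in names(entry$matures)) {
    db$mat[[macc]] <- entry$matures[[macc]]
    db$dead[[macc]] <- NULL
    log_event(db, lab, macc, "mature", "RESURRECTED",
              new_name = entry$matures[[macc]]$name,
              new_seq = mature_sequence(db, macc))
  }
  db$graveyard[[pacc]] <- NULL
}

db_to_snapshot <- function(db, lab) {
  precursors <- lapply(db$prec[sort_c(names(db$prec))], function(p) {
    precursor_record(
      accession = p$accession, name = p$name, sequence = p$sequence,
      description = paste(p$species_name, prec_to_mat_base(sub("^[a-z]+-", "", p$name)),
                          "stem-loop"),
      species_name = p$species_name, mature_features = p$features)
  })
  matures <- lapply(db$mat[sort_c(names(db$mat))], function(m) {
    mature_record(m$accession, m$name, mature_sequence(db, m$accession),
                  m$parents, provisional = FALSE)
  })
  dead <- lapply(db$dead[sort_c(names(db$dead))], function(d) {
    dead_entry(d$accession, d$last_name, d$forward_to)
  })
  release_snapshot(lab, precursors, matures, unname(dead), validate = FALSE)
}

#' Recover per-accession change events from a store's CHANGES table
#'
#' Inverse of the one-row-per-type persistence: groups CHANGES rows back into
#' one event per accession per release with a canonical `;`-joined type set —
#' the same shape as the simulator's ground-truth log.
#'
#' @param store an `event_store`.
#' @return data.frame with columns `release_label`, `accession`,
#'   `molecule_type`, `change_types`, `merge_target`.
#' @export
store_events <- function(store) {
  ch <- store$changes
  key <- paste(ch$release_label, ch$accession, sep = "\r")
  idx <- split(seq_len(nrow(ch)), key)
  out <- do.call(rbind, lapply(idx, function(rows) {
    mt <- ch$merge_target[rows]
    mt <- mt[!is.na(mt)]
    data.frame(
      release_label = ch$release_label[rows[1L]],
      accession = ch$accession[rows[1L]],
      molecule_type = ch$molecule_type[rows[1L]],
      change_types = paste(intersect(CHANGE_TYPES, ch$change_type[rows]),
                           collapse = ";"),
      merge_target = if (length(mt)) mt[1L] else NA_character_,
      stringsAsFactors = FALSE)
  }))
  out <- out[order(vapply(out$release_label, ordinal_key, 0), out$accession), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
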