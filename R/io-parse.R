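# Readers for the three miRBase release file dialects:
#   miRNA.dat  - EMBL-style flat file of precursor records with FT miRNA features
#   mature.fa  - FASTA of mature sequences, headers "name [accession] species..."
#   miRNA.dead - AC/ID/FW/CO blocks of removed entries, "//"-delimited
#
# Parsing is tolerant of dialect drift across old releases: required fields are
# ID/AC/SQ for precursors and the header name for matures; unknown line types
# are retained verbatim as opaque annotation, never errors.

read_lines_any <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (inherits(x, "connection")) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(as.character(x), "\n", fixed = TRUE), use.names = FALSE)
  }
}

#' Parse a miRNA.dat EMBL-style flat file of precursor records
#'
#' Records are `//`-delimited blocks of two-letter line types. `ID` carries the
#' precursor name, `AC` the accession, `DE` the description, `FT` the mature
#' miRNA features (location plus `/accession`, `/product`, `/evidence`
#' qualifiers; `/accession` is absent in releases predating mature accessions)
#' and `SQ` introduces the sequence, whose continuation lines are stripped of
#' digits and whitespace, T-to-U converted and uppercased. All other line types
#' are retained verbatim as opaque annotation.
#'
#' @param x file path, connection, or character vector of lines.
#' @param release_label release the file belongs to (recorded on errors only).
#' @return list of [precursor_record()] objects.
#' @export
#' @examples
#' block <- c(
#'   "ID   dme-mir-1    standard; RNA; DME; 71 BP.",
#'   "AC   MI0000116;",
#'   "DE   Drosophila melanogaster miR-1 stem-loop",
#'   "FT   miRNA           45..66",
#'   "FT                   /product=\"dme-miR-1\"",
#'   "SQ   Sequence 71 BP; 20 A; 12 C; 18 G; 0 T; 21 other;",
#'   paste0("     ugggaaaucg auucauaaag cuauauuaug aucuucuucc uguacuugga ",
#'          "uggaauguaa        60"),
#'   "     agaagugugu g                                                  71",
#'   "//")
#' parse_precursor_flatfile(block)[[1]]
parse_precursor_flatfile <- function(x, release_label = NA_character_) {
  lines <- read_lines_any(x)
  records <- list()
  block_start <- 1L
  i <- 1L
  n <- length(lines)
  current <- character(0)
  while (i <= n + 1L) {
    terminal <- i > n
    line <- if (terminal) "//" else lines[[i]]
    if (startsWith(line, "//")) {
      if (length(current) > 0L && any(nzchar(trimws(current)))) {
        records[[length(records) + 1L]] <-
          parse_precursor_block(current, block_start, release_label)
      }
      current <- character(0)
      block_start <- i + 1L
    } else {
      current <- c(current, line)
    }
    i <- i + 1L
  }
  records
}

parse_precursor_block <- function(lines, line_offset, release_label) {
  type <- substr(lines, 1L, 2L)
  body <- trimws(substr(lines, 6L, nchar(lines)))

  err <- function(msg, rel_line = 1L) {
    stop(sprintf("miRNA.dat parse error at line %d%s: %s",
                 line_offset + rel_line - 1L,
                 if (is.na(release_label)) "" else sprintf(" (release %s)", release_label),
                 msg), call. = FALSE)
  }

  id_idx <- which(type == "ID")
  if (length(id_idx) == 0L) err("record block lacks an ID line")
  name <- strsplit(body[id_idx[1L]], "\\s+")[[1]][1L]

  ac_idx <- which(type == "AC")
  if (length(ac_idx) == 0L) err(sprintf("record '%s' lacks an AC line", name))
  accession <- sub(";.*$", "", strsplit(body[ac_idx[1L]], "\\s+")[[1]][1L])

  de <- paste(body[type == "DE"], collapse = " ")

  sq_idx <- which(type == "SQ")
  if (length(sq_idx) == 0L) err(sprintf("record '%s' (%s) lacks an SQ line", name, accession))
  seq_lines <- lines[seq_len(length(lines)) > sq_idx[1L] & type == "  "]
  sequence <- gsub("[0-9[:space:]]", "", paste(seq_lines, collapse = ""))
  if (!nzchar(sequence)) {
    err(sprintf("record '%s' (%s) has an empty sequence body", name, accession), sq_idx[1L])
  }
  sequence <- normalize_rna(sequence, sprintf("precursor %s sequence", accession))

  # FT miRNA features: a location line then /qualifier continuation lines.
  features <- empty_features()
  ft_idx <- which(type == "FT")
  cur <- NULL
  cur_line <- NA_integer_
  flush_feature <- function(f) {
    if (is.null(f)) return(invisible())
    if (f$end > nchar(sequence) || f$start < 1L) {
      err(sprintf("record '%s' (%s): feature %d..%d outside sequence 1..%d",
                  name, accession, f$start, f$end, nchar(sequence)), cur_line)
    }
    features[nrow(features) + 1L, ] <<- list(
      f$accession %||% NA_character_, f$product %||% NA_character_,
      f$start, f$end, f$evidence %||% NA_character_)
  }
  for (j in ft_idx) {
    b <- body[j]
    if (grepl("^miRNA\\s", b)) {
      flush_feature(cur)
      loc <- regmatches(b, regexpr("\\d+\\.\\.\\d+", b))[1]
      if (is.na(loc) || !nzchar(loc)) {
        err(sprintf("record '%s' (%s): unparseable feature location '%s'",
                    name, accession, b), j)
      }
      se <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
      cur <- list(start = se[1L], end = se[2L])
      cur_line <- j
    } else if (!is.null(cur) && startsWith(b, "/")) {
      q <- sub("^/", "", b)
      key <- sub("=.*$", "", q)
      val <- if (grepl("=", q, fixed = TRUE)) gsub("^\"|\"$", "", sub("^[^=]*=", "", q)) else ""
      if (key == "accession") cur$accession <- val
      if (key == "product") cur$product <- val
      if (key == "evidence") cur$evidence <- val
      if (key == "experiment") cur$evidence <- paste(c(cur$evidence, val), collapse = "; ")
    }
  }
  flush_feature(cur)

  # everything that is not a consumed structural line is opaque annotation
  keep <- !(type %in% c("ID", "AC", "DE", "SQ", "FT", "  ", "XX", "FH")) &
    nzchar(trimws(lines))
  precursor_record(
    accession = accession, name = name, sequence = sequence,
    description = de, mature_features = features, annotations = lines[keep]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a mature.fa FASTA file of mature miRNA sequences
#'
#' Headers follow the dialect `>name accession species-and-product-words`; the
#' accession token is recognized by its `MIMAT` prefix and may be absent in
#' releases predating mature accessions. Bodies are uppercased and T-to-U
#' converted; multi-line bodies are concatenated.
#'
#' @param x file path, connection, or character vector of lines.
#' @return data.frame with columns `name`, `accession` (`NA` when absent),
#'   `species` (remaining header text) and `sequence`.
#' @export
parse_mature_fasta <- function(x) {
  lines <- read_lines_any(x)
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  set <- Biostrings::readBStringSet(tf)
  headers <- names(set)
  out <- data.frame(name = character(length(set)), accession = NA_character_,
                    species = "", sequence = "", stringsAsFactors = FALSE)
  for (i in seq_along(set)) {
    toks <- strsplit(trimws(headers[i]), "\\s+")[[1]]
    out$name[i] <- toks[1L]
    rest <- toks[-1L]
    if (length(rest) && grepl("^MIMAT\\d{7}$", rest[1L])) {
      out$accession[i] <- rest[1L]
      rest <- rest[-1L]
    }
    out$species[i] <- paste(rest, collapse = " ")
    out$sequence[i] <- normalize_rna(as.character(set[[i]]),
                                     sprintf("mature.fa entry '%s'", toks[1L]))
  }
  acc <- out$accession[!is.na(out$accession)]
  if (anyDuplicated(acc)) {
    stop(sprintf("duplicate mature accession(s) in mature.fa: %s",
                 paste(unique(acc[duplicated(acc)]), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Parse a miRNA.dead file of removed entries
#'
#' Records are `//`-delimited blocks of `AC` (required), `ID`, `FW` (forward
#' accession after a merge, optional) and `CO` (comment) lines. Molecule type
#' is inferred from the accession prefix (`MI` vs `MIMAT`).
#'
#' @param x file path, connection, or character vector of lines.
#' @return list of [dead_entry()] objects.
#' @export
parse_dead_file <- function(x) {
  lines <- read_lines_any(x)
  entries <- list()
  current <- character(0)
  flush <- function(block) {
    block <- block[nzchar(trimws(block))]
    if (!length(block)) return(NULL)
    type <- substr(block, 1L, 2L)
    body <- trimws(substr(block, 6L, nchar(block)))
    ac <- body[type == "AC"]
    if (!length(ac)) stop("miRNA.dead block lacks an AC line", call. = FALSE)
    ac <- sub(";.*$", "", strsplit(ac[1L], "\\s+")[[1]][1L])
    idv <- body[type == "ID"]
    fw <- body[type == "FW"]
    fw <- if (length(fw) && nzchar(fw[1L])) sub(";.*$", "", fw[1L]) else NA_character_
    co <- body[type == "CO"]
    dead_entry(
      accession = ac,
      last_name = if (length(idv)) idv[1L] else NA_character_,
      forward_to = fw,
      comment = if (length(co)) paste(co, collapse = " ") else NA_character_
    )
  }
  for (line in c(lines, "//")) {
    if (startsWith(line, "//")) {
      e <- flush(current)
      if (!is.null(e)) entries[[length(entries) + 1L]] <- e
      current <- character(0)
    } else {
      current <- c(current, line)
    }
  }
  entries
}

#' Load one miRBase release directory into a validated snapshot
#'
#' Expects `miRNA.dat` and `mature.fa` in `directory` (`miRNA.dead` optional).
#' Mature records are built by joining mature.fa entries to FT features — by
#' accession when present, else by product name plus sequence identity.
#' Matures without accessions (releases before mature accessions existed)
#' receive stable provisional identifiers, later replaced by retro-assignment.
#' Every mature sequence is cross-validated against the precursor substring at
#' its feature coordinates; a mismatch is surfaced as a warning and the
#' mature.fa sequence wins.
#'
#' @param directory path holding the release files.
#' @param release_label version string for the release.
#' @return a [release_snapshot()].
#' @export
load_release <- function(directory, release_label) {
  dat <- file.path(directory, "miRNA.dat")
  fa <- file.path(directory, "mature.fa")
  if (!file.exists(dat)) stop(sprintf("missing %s", dat), call. = FALSE)
  if (!file.exists(fa)) stop(sprintf("missing %s", fa), call. = FALSE)
  precursors <- parse_precursor_flatfile(dat, release_label)
  mature_tab <- parse_mature_fasta(fa)
  dead_path <- file.path(directory, "miRNA.dead")
  dead <- if (file.exists(dead_path)) parse_dead_file(dead_path) else list()
  assemble_snapshot(release_label, precursors, mature_tab, dead)
}

# Join mature.fa entries to precursor FT features and build mature records.
assemble_snapshot <- function(release_label, precursors, mature_tab, dead) {
  names(precursors) <- vapply(precursors, `[[`, "", "accession")
  matures <- list()
  orphans <- character(0)
  for (i in seq_len(nrow(mature_tab))) {
    nm <- mature_tab$name[i]
    acc <- mature_tab$accession[i]
    sq <- mature_tab$sequence[i]
    parents <- character(0)
    for (p in precursors) {
      ft <- p$mature_features
      if (!nrow(ft)) next
      hit <- if (!is.na(acc)) {
        !is.na(ft$mature_accession) & ft$mature_accession == acc
      } else {
        # join by product name; prefer coordinates whose substring matches
        by_name <- !is.na(ft$product) & ft$product == nm
        by_seq <- by_name & substr(rep(p$sequence, nrow(ft)), ft$start, ft$end) == sq
        if (any(by_seq)) by_seq else by_name
      }
      if (any(hit)) parents <- c(parents, p$accession)
    }
    if (!length(parents) && !is.na(acc)) {
      # accessioned entry whose features predate /accession qualifiers
      for (p in precursors) {
        ft <- p$mature_features
        if (!nrow(ft)) next
        by_name <- !is.na(ft$product) & ft$product == nm
        by_seq <- by_name & substr(rep(p$sequence, nrow(ft)), ft$start, ft$end) == sq
        hit <- if (any(by_seq)) by_seq else by_name
        if (any(hit)) {
          parents <- c(parents, p$accession)
          precursors[[p$accession]]$mature_features$mature_accession[hit] <- acc
        }
      }
    }
    if (!length(parents)) {
      orphans <- c(orphans, nm)
      next
    }
    if (is.na(acc)) {
      acc <- provisional_accession(species_of(nm), nm, sq)
      # backfill the joined features so provisional ids are consistent
      for (pa in parents) {
        ft <- precursors[[pa]]$mature_features
        rows <- which(is.na(ft$mature_accession) & ft$product == nm)
        if (length(rows)) {
          sub_ok <- substr(rep(precursors[[pa]]$sequence, length(rows)),
                           ft$start[rows], ft$end[rows]) == sq
          fill <- if (any(sub_ok)) rows[sub_ok] else rows[1L]
          precursors[[pa]]$mature_features$mature_accession[fill] <- acc
        }
      }
    }
    key <- acc
    if (!is.null(matures[[key]])) {
      matures[[key]]$parent_precursors <-
        sort_c(unique(c(matures[[key]]$parent_precursors, parents)))
    } else {
      matures[[key]] <- mature_record(acc, nm, sq, parents)
    }
  }
  if (length(orphans)) {
    stop(sprintf("mature.fa entries with no matching FT feature in release %s: %s",
                 release_label, paste(orphans, collapse = ", ")), call. = FALSE)
  }
  release_snapshot(release_label, precursors, matures, dead)
}
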