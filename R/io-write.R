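# Writers for the miRBase release dialects, plus batch-query / report I/O.
# Emitted files are bit-parseable by the package's own parsers (round-trip
# contract) and follow the dialect's layout: SQ blocks wrapped at 60 nt in
# 10-nt groups with trailing position numbers, FASTA bodies wrapped at 60.

#' Write a release snapshot as miRNA.dat, mature.fa and miRNA.dead files
#'
#' Refuses to write a snapshot violating its invariants. The emitted files
#' re-parse (via [load_release()]) to an equal snapshot.
#'
#' @param snapshot a [release_snapshot()].
#' @param directory output directory (created if needed).
#' @param mature_accessions write `MIMAT` accessions into mature.fa headers and
#'   FT `/accession` qualifiers. Set `FALSE` to emit the pre-accession dialect
#'   of early releases (provisional accessions are never written).
#' @return `directory`, invisibly.
#' @export
write_release <- function(snapshot, directory, mature_accessions = TRUE) {
  stopifnot(inherits(snapshot, "release_snapshot"))
  validate_snapshot(snapshot)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)

  writable_acc <- function(acc) {
    !is.na(acc) & mature_accessions & grepl("^MIMAT\\d{7}$", acc)
  }

  # --- miRNA.dat ---
  dat <- character(0)
  for (p in snapshot$precursors) {
    dat <- c(dat,
      sprintf("ID   %s    standard; RNA; %s; %d BP.", p$name,
              toupper(p$species_code), p$length_nt),
      "XX",
      sprintf("AC   %s;", p$accession),
      "XX",
      sprintf("DE   %s", if (nzchar(p$description)) p$description else p$name),
      "XX")
    if (length(p$annotations)) dat <- c(dat, p$annotations, "XX")
    ft <- p$mature_features
    if (nrow(ft)) {
      dat <- c(dat, "FH   Key             Location/Qualifiers", "FH")
      for (i in seq_len(nrow(ft))) {
        dat <- c(dat, sprintf("FT   miRNA           %d..%d", ft$start[i], ft$end[i]))
        if (writable_acc(ft$mature_accession[i])) {
          dat <- c(dat, sprintf("FT                   /accession=\"%s\"",
                                ft$mature_accession[i]))
        }
        if (!is.na(ft$product[i])) {
          dat <- c(dat, sprintf("FT                   /product=\"%s\"", ft$product[i]))
        }
        if (!is.na(ft$evidence[i])) {
          dat <- c(dat, sprintf("FT                   /evidence=%s", ft$evidence[i]))
        }
      }
      dat <- c(dat, "XX")
    }
    dat <- c(dat, sq_block(p$sequence), "//")
  }
  writeLines(dat, file.path(directory, "miRNA.dat"))

  # --- mature.fa ---
  fa <- character(0)
  for (m in snapshot$matures) {
    species_text <- mature_species_text(snapshot, m)
    header <- paste(c(m$name,
                      if (writable_acc(m$accession)) m$accession,
                      species_text), collapse = " ")
    fa <- c(fa, paste0(">", header), wrap_sequence(m$sequence, 60L))
  }
  writeLines(fa, file.path(directory, "mature.fa"))

  # --- miRNA.dead ---
  dd <- character(0)
  for (d in snapshot$dead) {
    dd <- c(dd, sprintf("AC   %s", d$accession))
    if (!is.na(d$last_name)) dd <- c(dd, sprintf("ID   %s", d$last_name))
    if (!is.na(d$forward_to)) dd <- c(dd, sprintf("FW   %s", d$forward_to))
    if (!is.na(d$comment)) dd <- c(dd, sprintf("CO   %s", d$comment))
    dd <- c(dd, "//")
  }
  writeLines(dd, file.path(directory, "miRNA.dead"))
  invisible(directory)
}

# binomial + product words for the FASTA header, taken from the first parent
mature_species_text <- function(snapshot, m) {
  for (pa in m$parent_precursors) {
    sn <- snapshot$precursors[[pa]]$species_name
    if (!is.na(sn) && nzchar(sn)) {
      return(paste(sn, sub(paste0("^", m$species_code, "-"), "", m$name)))
    }
  }
  character(0)
}

# EMBL SQ block: lowercase sequence, 60 nt per line in 10-nt groups, running
# position right-aligned at the line end.
sq_block <- function(sequence) {
  s <- tolower(sequence)
  n <- nchar(s)
  counts <- table(factor(strsplit(toupper(sequence), "")[[1]],
                         levels = c("A", "C", "G", "T")))
  header <- sprintf("SQ   Sequence %d BP; %d A; %d C; %d G; %d T; %d other;",
                    n, counts[["A"]], counts[["C"]], counts[["G"]], counts[["T"]],
                    n - sum(counts))
  lines <- character(0)
  pos <- 1L
  while (pos <= n) {
    end <- min(pos + 59L, n)
    chunk <- substr(s, pos, end)
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    body <- paste(groups, collapse = " ")
    lines <- c(lines, sprintf("     %-66s%7d", body, end))
    pos <- end + 1L
  }
  c(header, lines)
}

wrap_sequence <- function(sequence, width = 60L) {
  n <- nchar(sequence)
  substring(sequence, seq(1L, n, width), pmin(seq(width, n + width - 1L, width), n))
}

# Re-run the snapshot invariants (used by write_release's refuse-to-write rule).
validate_snapshot <- function(snapshot) {
  for (m in snapshot$matures) {
    missing <- setdiff(m$parent_precursors, names(snapshot$precursors))
    if (length(missing)) {
      stop(sprintf("snapshot invariant violation: mature %s references absent precursor %s",
                   m$accession, missing[1L]), call. = FALSE)
    }
  }
  for (p in snapshot$precursors) {
    if (nchar(p$sequence) != p$length_nt) {
      stop(sprintf("snapshot invariant violation: precursor %s length mismatch",
                   p$accession), call. = FALSE)
    }
    ft <- p$mature_features
    if (nrow(ft) && any(ft$start < 1L | ft$end > p$length_nt | ft$start > ft$end)) {
      stop(sprintf("snapshot invariant violation: precursor %s feature coordinates",
                   p$accession), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a batch query file (TSV)
#'
#' Expected header: `query` (required), `id_type`, `molecule_type`, `release`
#' (optional). Blank lines are skipped. Unknown `id_type` or `molecule_type`
#' tokens raise an error naming the offending line.
#'
#' @param x file path, connection, or character vector of lines.
#' @return data.frame with columns `raw_query`, `id_type`, `molecule_type`,
#'   `release_context` — one row per data line.
#' @export
read_batch_queries <- function(x) {
  lines <- read_lines_any(x)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("batch query file is empty", call. = FALSE)
  lines_kept <- lines[keep]
  orig_no <- which(keep)
  header <- strsplit(lines_kept[1L], "\t", fixed = TRUE)[[1]]
  header <- trimws(tolower(header))
  if (!"query" %in% header) {
    stop("batch query file header must contain a 'query' column", call. = FALSE)
  }
  col <- function(fields, nm) {
    i <- match(nm, header)
    if (is.na(i) || i > length(fields)) NA_character_ else trimws(fields[i])
  }
  out <- data.frame(raw_query = character(0), id_type = character(0),
                    molecule_type = character(0), release_context = character(0),
                    stringsAsFactors = FALSE)
  for (k in seq_along(lines_kept)[-1L]) {
    fields <- strsplit(lines_kept[k], "\t", fixed = TRUE)[[1]]
    q <- col(fields, "query")
    if (is.na(q) || !nzchar(q)) {
      stop(sprintf("line %d: empty query", orig_no[k]), call. = FALSE)
    }
    idt <- col(fields, "id_type")
    if (is.na(idt) || !nzchar(idt)) idt <- "auto"
    if (!idt %in% c("name", "accession", "sequence", "auto")) {
      stop(sprintf("line %d: unknown id_type '%s'", orig_no[k], idt), call. = FALSE)
    }
    mt <- col(fields, "molecule_type")
    if (is.na(mt) || !nzchar(mt)) mt <- "auto"
    if (!mt %in% c("mature", "precursor", "auto")) {
      stop(sprintf("line %d: unknown molecule_type '%s'", orig_no[k], mt), call. = FALSE)
    }
    rel <- col(fields, "release")
    if (!is.na(rel) && !nzchar(rel)) rel <- NA_character_
    out[nrow(out) + 1L, ] <- list(q, idt, mt, rel)
  }
  out
}

#' Write a tabular report as TSV or JSON
#'
#' @param rows data.frame to write.
#' @param path output file path.
#' @param format `"tsv"` or `"json"` (UTF-8, LF line endings).
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", na = "null", digits = NA)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#' @param path file path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      stringsAsFactors = FALSE, colClasses = "character", na.strings = "")
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
}
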