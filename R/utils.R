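# Internal helpers shared across modules.

#' Normalize a nucleotide sequence to the uppercase RNA alphabet
#'
#' Uppercases and converts T to U. Errors if the result contains characters
#' outside `{A,C,G,U,N}`.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return character vector of normalized RNA sequences.
#' @keywords internal
normalize_rna <- function(x, what = "sequence") {
  out <- chartr("T", "U", toupper(x))
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,U,T,N}: %s",
                 what, paste(utils::head(out[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Reverse complement of an RNA sequence
#' @param x a single RNA string over {A,C,G,U,N}.
#' @return the reverse complement as a plain string.
#' @keywords internal
rna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

# C-locale (radix) lexicographic sort: deterministic across platforms/locales.
sort_c <- function(x) {
  if (is.null(x)) return(character(0))
  sort(x, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

# Deterministic 31-bit polynomial string hash (djb2 variant, exact in doubles:
# intermediate products stay below 2^53). Used for stable provisional ids.
string_hash31 <- function(s) {
  h <- 5381
  for (c in utf8ToInt(s)) h <- (h * 33 + c) %% 2147483647
  h
}

#' Stable provisional accession for an unaccessioned mature record
#'
#' Content-derived, so the same (species, name, sequence) always yields the
#' same identifier regardless of what else is in the release.
#' @keywords internal
provisional_accession <- function(species_code, name, sequence) {
  key <- paste(species_code, name, sequence, sep = "\t")
  sprintf("PROV%010d", string_hash31(key))
}

#' Parse a release label into a numeric (major, minor) ordinal
#'
#' Labels are version strings such as `"5.1"`, `"9.2"` or `"21"`. Ordering is
#' numeric on the pair, so `"9.2" < "10.0" < "21"`.
#'
#' @param label release label string.
#' @return numeric vector `c(major, minor)`.
#' @export
#' @examples
#' release_ordinal("9.2")
#' release_ordinal("21")
release_ordinal <- function(label) {
  parts <- strsplit(as.character(label), ".", fixed = TRUE)[[1]]
  if (length(parts) < 1L || length(parts) > 2L || anyNA(suppressWarnings(as.numeric(parts)))) {
    stop(sprintf("invalid release label: '%s'", label), call. = FALSE)
  }
  major <- as.numeric(parts[1L])
  minor <- if (length(parts) == 2L) as.numeric(parts[2L]) else 0
  c(major = major, minor = minor)
}

# Single sortable number for a label; minors in miRBase never reach 1000.
ordinal_key <- function(label) {
  o <- release_ordinal(label)
  o[[1L]] * 1000 + o[[2L]]
}

# Species code = name prefix before the first hyphen.
species_of <- function(name) sub("-.*$", "", name)

# Collapse a set-valued field to a canonical string for comparison/storage.
join_set <- function(x) paste(sort_c(unique(x[!is.na(x) & nzchar(x)])), collapse = ";")

split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
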