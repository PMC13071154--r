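#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of protein sequences. The sequence id is
#' the header token before the first whitespace, record order is preserved,
#' and duplicate ids or records without residues are rejected.
#'
#' @param path Path to a FASTA file.
#'
#' @return A tibble with columns `id` (character), `residues` (character,
#'   amino-acid letters) and `length` (integer residue count), one row per
#'   record.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKV", ">b", "GG"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  if (file.size(path) == 0) {
    return(tibble(id = character(), residues = character(), length = integer()))
  }
  check_fasta_records(path)
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("Duplicate sequence id(s) in %s: %s",
                  path, paste(dup, collapse = ", ")))
  }
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    bad <- ids[widths == 0L][1L]
    abort(sprintf("FASTA record '%s' has a header but no residues.", bad))
  }
  tibble(
    id = ids,
    residues = unname(as.character(set)),
    length = as.integer(widths)
  )
}

# Cheap pre-scan so malformed records are reported with a line number
# (Biostrings is permissive about empty records).
check_fasta_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  headers <- grepl("^>", lines)
  if (length(lines) > 0L && !headers[1L] && any(nzchar(trimws(lines)))) {
    abort(sprintf("Malformed FASTA at line 1 of %s: residues before any header.",
                  path))
  }
  idx <- which(headers)
  for (i in idx) {
    nxt <- if (i < length(lines)) lines[i + 1L] else ""
    if (grepl("^>", nxt) || !nzchar(trimws(nxt))) {
      abort(sprintf("Malformed FASTA at line %d of %s: header without sequence.",
                    i, path))
    }
  }
  invisible(TRUE)
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences A tibble with columns `id` and `residues`, as returned by
#'   [read_fasta()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  if (anyDuplicated(sequences$id)) {
    abort("Sequence ids must be unique when writing FASTA.")
  }
  set <- Biostrings::AAStringSet(setNames(sequences$residues, sequences$id))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Keep sequences strictly shorter than a length cutoff
#'
#' Protein language models have a positional limit, so the pipeline keeps
#' only proteins with fewer than `max_len` residues (strict inequality).
#' Order is preserved and the filter is idempotent.
#'
#' @param sequences A sequence tibble from [read_fasta()].
#' @param max_len Length cutoff; sequences with `length < max_len` are kept.
#'   Defaults to 1024, the positional limit of the embedders this pipeline
#'   targets.
#'
#' @return The filtered sequence tibble.
#' @export
filter_by_length <- function(sequences, max_len = 1024L) {
  stopifnot_scalar_int(max_len, "max_len", min = 1L)
  dplyr::filter(sequences, .data$length < max_len)
}
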