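#' Build a dataset split from a record table
#'
#' A split assigns every sequence id to exactly one partition (`train`,
#' `dev` or `test`) and carries the family (domain) annotations used as
#' labels. One row per annotated domain: multi-domain sequences have several
#' rows, all in the same partition. The family index is the bijection between
#' family accessions and class indices `1..K`; families seen only in dev or
#' test are still indexed (a classifier can then never predict them, and they
#' count as false negatives).
#'
#' @param records A data frame with columns `id`, `partition`
#'   (one of `"train"`, `"dev"`, `"test"`), `family`, and optionally `start`
#'   and `end` (1-based inclusive domain span; `NA` allowed when spans are
#'   unknown).
#' @param families Optional character vector fixing the family order of the
#'   index; defaults to sorted unique families across all partitions.
#'
#' @return An object of class `etpfam_split`: a list with `records` (tibble)
#'   and `family_index` (tibble with columns `family`, `class`).
#' @export
dataset_split <- function(records, families = NULL) {
  records <- as_tibble(records)
  needed <- c("id", "partition", "family")
  if (!all(needed %in% names(records))) {
    abort("Split records need columns id, partition, family.")
  }
  if (!"start" %in% names(records)) records$start <- NA_integer_
  if (!"end" %in% names(records)) records$end <- NA_integer_
  records <- records[, c("id", "partition", "family", "start", "end")]
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  bad <- setdiff(unique(records$partition), c("train", "dev", "test"))
  if (length(bad)) {
    abort(sprintf("Unknown partition(s): %s", paste(bad, collapse = ", ")))
  }
  multi <- records |>
    dplyr::distinct(.data$id, .data$partition) |>
    dplyr::count(.data$id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi)) {
    abort(sprintf("Sequence id(s) in more than one partition: %s",
                  paste(multi$id, collapse = ", ")))
  }
  span_bad <- !is.na(records$start) & !is.na(records$end) &
    (records$start < 1L | records$end < records$start)
  if (any(span_bad)) {
    abort("Domain spans must satisfy 1 <= start <= end.")
  }
  families <- families %||% sort(unique(records$family))
  if (!all(records$family %in% families)) {
    abort("`families` must cover every family present in the records.")
  }
  structure(
    list(
      records = records,
      family_index = tibble(family = families,
                            class = seq_along(families))
    ),
    class = "etpfam_split"
  )
}

#' @export
print.etpfam_split <- function(x, ...) {
  parts <- table(dplyr::distinct(x$records, .data$id, .data$partition)$partition)
  cat(sprintf(
    "<etpfam_split> %d sequences, %d families (train %d / dev %d / test %d)\n",
    dplyr::n_distinct(x$records$id), nrow(x$family_index),
    parts["train"] %||% 0L, parts["dev"] %||% 0L, parts["test"] %||% 0L))
  invisible(x)
}

#' Read or write a split table
#'
#' Split tables are tab-separated with header
#' `id  partition  family  start  end`, one row per annotated domain.
#'
#' @param path File path.
#' @param families Optional fixed family order (see [dataset_split()]).
#' @return `read_split()` returns an `etpfam_split`; `write_split()` returns
#'   `path` invisibly.
#' @export
read_split <- function(path, families = NULL) {
  records <- readr::read_tsv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      partition = readr::col_character(),
      family = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer()
    )
  )
  dataset_split(records, families = families)
}

#' @param split An `etpfam_split`.
#' @rdname read_split
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "etpfam_split"))
  readr::write_tsv(split$records, path)
  invisible(path)
}

#' Remove duplicated sequences across and within partitions
#'
#' A residue string occurring in two or more partitions would leak label
#' information between train, dev and test, so every occurrence of such a
#' string is removed from the dataset (the whole protein is dropped, not just
#' the extra copy). Within a single partition, the first occurrence is kept
#' and later copies dropped.
#'
#' @param split An `etpfam_split`.
#' @param sequences Sequence tibble ([read_fasta()]) covering the split's ids.
#'
#' @return A list with `split` (the cleaned `etpfam_split`, family index
#'   preserved), `sequences` (the cleaned sequence tibble) and `removed`
#'   (tibble of `id`, `partition`, `reason` for every dropped sequence).
#' @export
deduplicate_across_partitions <- function(split, sequences) {
  stopifnot(inherits(split, "etpfam_split"))
  ids <- dplyr::distinct(split$records, .data$id, .data$partition)
  missing <- setdiff(ids$id, sequences$id)
  if (length(missing)) {
    abort(sprintf("Sequences missing for split id(s): %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  seqs <- dplyr::inner_join(sequences, ids, by = "id")
  grp <- seqs |>
    dplyr::group_by(.data$residues) |>
    dplyr::mutate(
      n_partitions = dplyr::n_distinct(.data$partition),
      occurrence = dplyr::row_number()
    ) |>
    dplyr::ungroup()
  removed <- grp |>
    dplyr::filter(.data$n_partitions > 1L | .data$occurrence > 1L) |>
    dplyr::mutate(reason = ifelse(.data$n_partitions > 1L,
                                  "cross-partition duplicate",
                                  "within-partition duplicate")) |>
    dplyr::select("id", "partition", "reason")
  keep_ids <- setdiff(ids$id, removed$id)
  clean_records <- dplyr::filter(split$records, .data$id %in% keep_ids)
  clean_split <- dataset_split(clean_records,
                               families = split$family_index$family)
  list(
    split = clean_split,
    sequences = dplyr::filter(sequences, .data$id %in% keep_ids),
    removed = removed
  )
}

# Per-sequence labels of one partition: tibble(id, family, class, start, end).
split_partition <- function(split, partition) {
  stopifnot(inherits(split, "etpfam_split"))
  split$records |>
    dplyr::filter(.data$partition == !!partition) |>
    dplyr::left_join(split$family_index, by = "family")
}
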