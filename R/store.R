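#' Embedding stores
#'
#' An embedding store persists per-residue embedding tracks so that single
#' sequences can be retrieved by id without loading the whole dataset, as
#' required during window sampling. The store is a directory container: a
#' JSON manifest (embedder name, dimension, id -> file map) plus one binary
#' matrix file per sequence.
#'
#' @param embedded A list of [embedded_sequence()] objects with unique ids.
#' @param path Directory to create (must not already contain a store).
#' @param embedder_name Name recorded in the manifest.
#'
#' @return `write_embedding_store()` returns an `embedding_store` handle;
#'   `embedding_store()` opens an existing one.
#' @name embedding_store
NULL

#' @rdname embedding_store
#' @export
write_embedding_store <- function(embedded, path, embedder_name = "synthetic") {
  ids <- vapply(embedded, function(e) e$id, character(1))
  if (anyDuplicated(ids)) abort("Embedded sequence ids must be unique.")
  dims <- vapply(embedded, function(e) nrow(e$matrix), integer(1))
  if (length(unique(dims)) > 1L) {
    abort("All tracks in a store must share one embedding dimension.")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- if (length(ids)) sprintf("seq_%05d.bin", seq_along(ids)) else character()
  for (i in seq_along(embedded)) {
    write_track(embedded[[i]]$matrix, file.path(path, files[i]))
  }
  manifest <- list(
    format = "etpfam-embedding-store-v1",
    embedder = embedder_name,
    dim = if (length(dims)) dims[[1L]] else NA_integer_,
    ids = as.list(ids),
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  embedding_store(path)
}

#' @rdname embedding_store
#' @export
embedding_store <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    abort(sprintf("No embedding store manifest at %s", path))
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  structure(
    list(path = path,
         embedder = manifest$embedder,
         dim = manifest$dim,
         ids = as.character(manifest$ids),
         files = setNames(as.character(manifest$files),
                          as.character(manifest$ids))),
    class = "embedding_store"
  )
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> %s: %d track(s), E=%s, embedder=%s\n",
              x$path, length(x$ids), x$dim, x$embedder))
  invisible(x)
}

#' @rdname embedding_store
#' @param store An `embedding_store` handle.
#' @param id Sequence id to retrieve.
#' @export
store_ids <- function(store) store$ids

#' @rdname embedding_store
#' @export
read_embedding <- function(store, id) {
  stopifnot(inherits(store, "embedding_store"))
  f <- store$files[id]
  if (is.na(f)) abort(sprintf("Id '%s' not found in embedding store.", id))
  embedded_sequence(id, read_track(file.path(store$path, f)))
}

#' Load tracks from a store, optionally attaching split labels
#'
#' @param store An `embedding_store`.
#' @param ids Sequence ids to load (default: all).
#' @param split Optional [dataset_split()] supplying domain annotations.
#' @return A named list of [embedded_sequence()] objects.
#' @export
load_embeddings <- function(store, ids = store_ids(store), split = NULL) {
  ann_by_id <- NULL
  if (!is.null(split)) {
    ann <- split$records |>
      dplyr::left_join(split$family_index, by = "family")
    ann_by_id <- base::split(ann[, c("family", "class", "start", "end")],
                             ann$id)
  }
  out <- lapply(ids, function(id) {
    e <- read_embedding(store, id)
    if (!is.null(ann_by_id) && !is.null(ann_by_id[[id]])) {
      e$domains <- as_tibble(ann_by_id[[id]])
    }
    e
  })
  setNames(out, ids)
}

# Binary track format: int32 E, int32 L, then E*L doubles column-major,
# little-endian. Bit-exact round trip for finite doubles.
write_track <- function(mat, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(as.integer(dim(mat)), con, size = 4L, endian = "little")
  writeBin(as.vector(mat), con, size = 8L, endian = "little")
  invisible(file)
}

read_track <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  d <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  vals <- readBin(con, "double", n = d[1L] * d[2L], size = 8L,
                  endian = "little")
  matrix(vals, nrow = d[1L], ncol = d[2L])
}
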