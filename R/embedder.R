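#' Describe an embedder
#'
#' An embedder turns a protein sequence into a per-residue embedding track
#' (an `E x L` real matrix). The package ships a deterministic synthetic
#' embedder used for testing and benchmarking; adapters for external protein
#' language models (`esm2`, E = 1280; `prott5`, E = 1024) are declared here
#' but require the corresponding external tooling and are not used by the
#' test suite.
#'
#' @param name One of `"synthetic"`, `"esm2"`, `"prott5"`.
#' @param dim Embedding dimension `E`. Defaults: 16 for `synthetic`,
#'   1280 for `esm2`, 1024 for `prott5`.
#' @param seed Integer seed making the synthetic embedder a pure function of
#'   `(residues, seed)`.
#'
#' @return An `embedder_spec` list with fields `name`, `dim`, `seed`.
#' @export
embedder_spec <- function(name = "synthetic", dim = NULL, seed = 1L) {
  known <- c(synthetic = 16L, esm2 = 1280L, prott5 = 1024L)
  if (!name %in% names(known)) {
    abort(sprintf("Unknown embedder '%s'; known: %s",
                  name, paste(names(known), collapse = ", ")))
  }
  dim <- as.integer(dim %||% known[[name]])
  stopifnot_scalar_int(dim, "dim", 1L)
  structure(list(name = name, dim = dim, seed = as.integer(seed)),
            class = "embedder_spec")
}

#' Construct an embedded sequence
#'
#' @param id Sequence identifier.
#' @param matrix An `E x L` numeric matrix (embedding dimension by residue).
#' @param domains Optional tibble of domain annotations with columns
#'   `family`, `class`, `start`, `end` (1-based inclusive spans).
#'
#' @return An `embedded_sequence` object.
#' @export
embedded_sequence <- function(id, matrix, domains = NULL) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (!all(is.finite(matrix))) {
    abort(sprintf("Embedding track for '%s' contains non-finite values.", id))
  }
  structure(list(id = id, matrix = matrix, domains = domains),
            class = "embedded_sequence")
}

#' @export
print.embedded_sequence <- function(x, ...) {
  cat(sprintf("<embedded_sequence> %s: E=%d x L=%d, %d domain(s)\n",
              x$id, nrow(x$matrix), ncol(x$matrix),
              if (is.null(x$domains)) 0L else nrow(x$domains)))
  invisible(x)
}

#' Embed one protein sequence
#'
#' The synthetic embedder hashes the 5-mer centred on each residue (edges
#' padded) to a pseudo-random unit-variance Gaussian vector, so identical
#' 5-mers map to identical columns. This mimics the local contextuality of a
#' protein language model while being dependency-free and fully deterministic.
#'
#' @param id Sequence id.
#' @param residues Amino-acid string.
#' @param spec An [embedder_spec()]. Only `"synthetic"` runs without external
#'   tooling.
#' @param domains Optional domain annotation tibble attached to the result.
#' @param cache Optional environment reused across calls to memoise 5-mer
#'   columns within a dataset.
#'
#' @return An [embedded_sequence()] with a `spec$dim x nchar(residues)` track.
#' @export
embed_sequence <- function(id, residues, spec = embedder_spec(),
                           domains = NULL, cache = NULL) {
  stopifnot(inherits(spec, "embedder_spec"))
  if (!nzchar(residues)) abort("Cannot embed an empty sequence.")
  if (spec$name != "synthetic") {
    abort(sprintf(
      "Embedder '%s' is an external adapter; compute its tracks with the %s",
      spec$name, "external tool and load them with write_embedding_store()."))
  }
  L <- nchar(residues)
  padded <- paste0("--", residues, "--")
  kmers <- substring(padded, seq_len(L), seq_len(L) + 4L)
  cache <- cache %||% new.env(parent = emptyenv())
  mat <- matrix(0, nrow = spec$dim, ncol = L)
  for (n in seq_len(L)) {
    km <- kmers[n]
    col <- cache[[km]]
    if (is.null(col)) {
      col <- with_seed(derive_seed(spec$seed, "kmer", km), rnorm(spec$dim))
      cache[[km]] <- col
    }
    mat[, n] <- col
  }
  embedded_sequence(id, mat, domains)
}

#' Embed a whole sequence table
#'
#' @param sequences Sequence tibble from [read_fasta()].
#' @param spec An [embedder_spec()].
#' @param split Optional [dataset_split()]; when given, each embedded
#'   sequence carries its domain annotations (with class indices).
#'
#' @return A named list of [embedded_sequence()] objects, in input order.
#' @export
embed_dataset <- function(sequences, spec = embedder_spec(), split = NULL) {
  cache <- new.env(parent = emptyenv())
  ann <- if (!is.null(split)) {
    split$records |>
      dplyr::left_join(split$family_index, by = "family") |>
      dplyr::group_by(.data$id) |>
      dplyr::group_split()
  }
  ann_by_id <- if (!is.null(ann)) {
    setNames(ann, vapply(ann, function(d) d$id[1L], character(1)))
  }
  out <- lapply(seq_len(nrow(sequences)), function(i) {
    id <- sequences$id[i]
    dom <- if (!is.null(ann_by_id) && !is.null(ann_by_id[[id]])) {
      ann_by_id[[id]][, c("family", "class", "start", "end")]
    }
    embed_sequence(id, sequences$residues[i], spec,
                   domains = dom, cache = cache)
  })
  setNames(out, sequences$id)
}
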