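# Shared in-code fixtures: everything is generated at test time.

# A random position score track with softmax rows.
random_track <- function(n_pos, K, seq_length = 4L * n_pos,
                         sequence_id = "s1", model_id = "m1") {
  z <- matrix(rnorm(n_pos * K), n_pos, K)
  position_score_track(
    sequence_id = sequence_id, model_id = model_id,
    positions = sort(sample.int(seq_length, n_pos)) - 1L,
    scores = exp(z) / rowSums(exp(z)),
    seq_length = seq_length
  )
}

# A random complete score block (n sequences x I models x K classes),
# rows softmax-normalized per model.
random_block <- function(n, I, K) {
  arr <- array(rnorm(n * I * K), dim = c(n, I, K))
  for (i in seq_len(I)) {
    e <- exp(arr[, i, , drop = FALSE])
    arr[, i, ] <- e[, 1, ] / rowSums(matrix(e, n, K))
  }
  structure(list(scores = arr,
                 sequence_ids = sprintf("s%04d", seq_len(n)),
                 model_ids = sprintf("m%02d", seq_len(I)),
                 method = "synthetic"),
            class = "etpfam_score_block")
}

# An embedded sequence whose track is noise + a class motif over the whole
# length; label attached as a single domain.
motif_sequence <- function(id, L, E, motif, class, family = NULL,
                           noise_sd = 0.2) {
  if (is.null(family)) family <- sprintf("FAM%02d", class)
  mat <- matrix(rnorm(E * L, sd = noise_sd), E, L) + motif
  embedded_sequence(id, mat,
                    domains = tibble::tibble(family = family, class = class,
                                             start = 1L, end = L))
}

# A tiny two-class labeled dataset where the label is carried by the sign
# of embedding coordinate 1.
toy_two_class_set <- function(n, L, E, signal = 2, noise_sd = 0.2,
                              prefix = "t") {
  lapply(seq_len(n), function(j) {
    class <- 1L + (j %% 2L)
    motif <- rep(0, E)
    motif[1L] <- if (class == 1L) signal else -signal
    motif_sequence(sprintf("%s%04d", prefix, j), L, E, motif, class,
                   noise_sd = noise_sd)
  })
}

# Sequence tibble from residue strings.
seq_tbl <- function(ids, residues) {
  tibble::tibble(id = ids, residues = residues,
                 length = nchar(residues))
}

# 0-based training-window starts considered valid for a sequence.
valid_starts_for_test <- function(e, W) {
  etpfam:::valid_training_starts(ncol(e$matrix), W,
                                 dplyr::arrange(e$domains, start, end))
}

# Cache for the expensive end-to-end demo runs shared by the acceptance
# tests (same seed -> same result object and artifact directory).
demo_cache <- new.env(parent = emptyenv())
demo_run_cached <- function(seed) {
  key <- as.character(seed)
  if (is.null(demo_cache[[key]])) {
    out_dir <- file.path(tempdir(), sprintf("etpfam_demo_seed%s", key))
    demo_cache[[key]] <- suppressMessages(
      run_demo(out_dir = out_dir, seed = seed, quiet = TRUE))
  }
  demo_cache[[key]]
}
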