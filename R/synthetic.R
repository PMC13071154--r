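#' Specification of a synthetic benchmark
#'
#' The generator emulates the statistical structure the classifier assumes
#' in real protein-family data: per-family positional motif signal embedded
#' in background noise, heavy class imbalance (power-law family sizes,
#' smallest families down to a couple of members), multi-domain sequences
#' carrying two distinct family motifs, and a train/dev/test partition.
#' Each sequence's embedding track is background Gaussian noise plus the
#' family's motif vector added over the annotated domain span; domains cover
#' most of the sequence, as Pfam domains typically do in the proteins of
#' this task.
#'
#' @param n_families Number of families `K` (default 12).
#' @param n_sequences Total sequences (default 300).
#' @param embed_dim Embedding dimension `E` (default 16).
#' @param motif_scale L2 norm of each family's motif vector (default 1).
#' @param noise_sd Per-entry background noise SD (default 0.25). The default
#'   signal-to-noise keeps the task learnable by a small model while leaving
#'   per-window ambiguity.
#' @param length_range Min/max sequence length (default `c(60, 160)`).
#' @param size_power Power-law exponent of family sizes (default 1);
#'   family `k` gets weight `k^-size_power`.
#' @param size_min Minimum family size (default 6, so every family can reach
#'   all three partitions).
#' @param multi_domain_fraction Fraction of sequences carrying a second,
#'   distinct family domain (default 0.1).
#' @param partition_fractions Named train/dev/test fractions summing to 1.
#' @param seed Integer seed; everything downstream is a pure function of it.
#'
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_families = 12L, n_sequences = 300L,
                           embed_dim = 16L, motif_scale = 1,
                           noise_sd = 0.25, length_range = c(60L, 160L),
                           size_power = 1, size_min = 6L,
                           multi_domain_fraction = 0.1,
                           partition_fractions = c(train = 0.7, dev = 0.15,
                                                   test = 0.15),
                           seed = 1L) {
  stopifnot(length(length_range) == 2L, length_range[1L] <= length_range[2L],
            multi_domain_fraction >= 0, multi_domain_fraction <= 1)
  if (abs(sum(partition_fractions) - 1) > 1e-8) {
    abort("Partition fractions must sum to 1.")
  }
  if (multi_domain_fraction > 0 && length_range[1L] < 24L) {
    abort("Two domains cannot fit: raise the minimum sequence length to >= 24.")
  }
  if (n_sequences < n_families * size_min) {
    abort("Too few sequences for the requested minimum family size.")
  }
  structure(list(n_families = as.integer(n_families),
                 n_sequences = as.integer(n_sequences),
                 embed_dim = as.integer(embed_dim),
                 motif_scale = motif_scale, noise_sd = noise_sd,
                 length_range = as.integer(length_range),
                 size_power = size_power, size_min = as.integer(size_min),
                 multi_domain_fraction = multi_domain_fraction,
                 partition_fractions = partition_fractions,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

# Power-law family sizes summing exactly to n_sequences.
family_sizes <- function(spec) {
  K <- spec$n_families
  w <- (seq_len(K))^(-spec$size_power)
  sizes <- pmax(spec$size_min, floor(w / sum(w) * spec$n_sequences))
  diff <- spec$n_sequences - sum(sizes)
  i <- 1L
  while (diff != 0L) {
    step <- sign(diff)
    if (step < 0 && sizes[i] <= spec$size_min) {
      i <- i %% K + 1L
      next
    }
    sizes[i] <- sizes[i] + step
    diff <- diff - step
    i <- i %% K + 1L
  }
  sizes
}

#' Generate a synthetic benchmark dataset
#'
#' @param spec A [benchmark_spec()].
#' @param out_dir Optional directory; when given, writes `sequences.fasta`,
#'   `split.tsv` and an embedding store under `store/`, all byte-identical
#'   for the same spec.
#'
#' @return A list with `sequences` (tibble), `split` ([dataset_split()]),
#'   `embedded` (named list of [embedded_sequence()] with labels attached),
#'   `motifs` (E x K matrix), and `paths` when `out_dir` is given.
#' @export
generate_benchmark <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "benchmark_spec"))
  K <- spec$n_families
  E <- spec$embed_dim
  families <- sprintf("SF%05d", seq_len(K))
  sizes <- family_sizes(spec)
  n <- spec$n_sequences
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

  with_seed(derive_seed(spec$seed, "benchmark"), {
    motifs <- matrix(rnorm(E * K), E, K)
    motifs <- sweep(motifs, 2L, sqrt(colSums(motifs^2)) / spec$motif_scale,
                    "/")
    fam_of <- rep(seq_len(K), times = sizes)
    lens <- sample(spec$length_range[1L]:spec$length_range[2L], n,
                   replace = TRUE)
    residues <- vapply(lens, function(L) {
      paste(sample(aa, L, replace = TRUE), collapse = "")
    }, character(1))
    ids <- sprintf("SEQ%05d", seq_len(n))
    multi <- runif(n) < spec$multi_domain_fraction

    records <- vector("list", n)
    tracks <- vector("list", n)
    for (s in seq_len(n)) {
      L <- lens[s]
      k1 <- fam_of[s]
      track <- matrix(rnorm(E * L, sd = spec$noise_sd), E, L)
      if (multi[s] && K > 1L) {
        k2 <- sample(setdiff(seq_len(K), k1), 1L)
        half <- L %/% 2L
        s1 <- sample.int(max(1L, round(0.1 * half)), 1L)
        e1 <- half - sample.int(max(1L, round(0.1 * half)), 1L)
        s2 <- half + sample.int(max(1L, round(0.1 * half)), 1L)
        e2 <- L - sample.int(max(1L, round(0.1 * half)), 1L) + 1L
        e2 <- min(e2, L)
        doms <- tibble(family = families[c(k1, k2)],
                       start = c(s1, s2), end = c(e1, e2))
        track[, s1:e1] <- track[, s1:e1] + motifs[, k1]
        track[, s2:e2] <- track[, s2:e2] + motifs[, k2]
      } else {
        s1 <- sample.int(max(1L, floor(0.15 * L)), 1L)
        e1 <- L - sample.int(max(1L, floor(0.15 * L)), 1L) + 1L
        doms <- tibble(family = families[k1], start = s1, end = min(e1, L))
        track[, doms$start:doms$end] <- track[, doms$start:doms$end] +
          motifs[, k1]
      }
      records[[s]] <- dplyr::mutate(doms, id = ids[s], .before = 1L)
      tracks[[s]] <- track
    }

    # stratified partition: first three members of each family go one to
    # each partition, the rest follow the requested fractions
    partition <- character(n)
    for (k in seq_len(K)) {
      members <- sample(which(fam_of == k))
      first <- c("train", "dev", "test")[seq_len(min(3L, length(members)))]
      partition[members[seq_along(first)]] <- first
      rest <- members[-seq_along(first)]
      if (length(rest)) {
        partition[rest] <- sample(names(spec$partition_fractions),
                                  length(rest), replace = TRUE,
                                  prob = spec$partition_fractions)
      }
    }

    sequences <- tibble(id = ids, residues = residues,
                        length = as.integer(lens))
    rec <- dplyr::bind_rows(records) |>
      dplyr::mutate(partition = partition[match(.data$id, ids)]) |>
      dplyr::select("id", "partition", "family", "start", "end")
    split <- dataset_split(rec, families = families)
    ann <- split$records |>
      dplyr::left_join(split$family_index, by = "family")
    ann_by_id <- base::split(ann[, c("family", "class", "start", "end")],
                             ann$id)
    embedded <- lapply(seq_len(n), function(s) {
      embedded_sequence(ids[s], tracks[[s]],
                        domains = as_tibble(ann_by_id[[ids[s]]]))
    })
    names(embedded) <- ids

    out <- list(sequences = sequences, split = split, embedded = embedded,
                motifs = motifs)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      fasta <- file.path(out_dir, "sequences.fasta")
      tsv <- file.path(out_dir, "split.tsv")
      store_dir <- file.path(out_dir, "store")
      write_fasta(sequences, fasta)
      write_split(split, tsv)
      write_embedding_store(embedded, store_dir, embedder_name = "benchmark")
      out$paths <- list(fasta = fasta, split = tsv, store = store_dir)
    }
    out
  })
}

#' Specification of a synthetic base-model score block
#'
#' Drives the ensemble layer directly, without training any model: for a
#' sequence of true family `k`, model `i`'s score vector has its argmax at
#' `k` with probability `p_ik` and at a designated confusion target
#' otherwise, softened to a probability vector at the given temperature.
#' This reproduces, in a controlled way, the regime where individual models
#' are reliable only on some families and a per-family combiner can learn
#' which model to trust for each family.
#'
#' @param n_models Number of base models `I`.
#' @param n_classes Number of families `K`.
#' @param reliability `I x K` matrix of `p_ik` in `[0, 1]`, or a scalar
#'   recycled to all entries.
#' @param confusion Optional `I x K` integer matrix of confusion targets
#'   (the class predicted when a model errs); default: the next class,
#'   `k %% K + 1`.
#' @param temperature Softmax temperature for the score vectors (default 1).
#' @param jitter SD of the background logit noise (default 0.5).
#' @param seed Integer seed.
#'
#' @return A `score_block_spec` list.
#' @export
score_block_spec <- function(n_models, n_classes, reliability,
                             confusion = NULL, temperature = 1,
                             jitter = 0.5, seed = 1L) {
  I <- as.integer(n_models); K <- as.integer(n_classes)
  if (length(reliability) == 1L) {
    reliability <- matrix(reliability, I, K)
  }
  stopifnot(all(dim(reliability) == c(I, K)),
            all(reliability >= 0 & reliability <= 1))
  if (is.null(confusion)) {
    confusion <- matrix(rep(seq_len(K) %% K + 1L, each = I), I, K)
  }
  stopifnot(all(dim(confusion) == c(I, K)))
  if (K > 1L && any(confusion == matrix(rep(seq_len(K), each = I), I, K))) {
    abort("Confusion targets must differ from the true class.")
  }
  structure(list(n_models = I, n_classes = K, reliability = reliability,
                 confusion = confusion, temperature = temperature,
                 jitter = jitter, seed = as.integer(seed)),
            class = "score_block_spec")
}

#' Generate a synthetic score block with known ground truth
#'
#' @param spec A [score_block_spec()].
#' @param labels Integer vector of true classes, one per sequence (sequence
#'   ids are generated as `R00001, ...` in this order).
#' @return A list with `block` (an [score_block()]) and `labels` (tibble of
#'   `sequence_id`, `class` aligned with the block).
#' @export
generate_score_block <- function(spec, labels) {
  stopifnot(inherits(spec, "score_block_spec"))
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > spec$n_classes)) {
    abort("Labels must be class indices in 1..K.")
  }
  n <- length(labels)
  I <- spec$n_models; K <- spec$n_classes
  ids <- sprintf("R%05d", seq_len(n))
  arr <- array(0, dim = c(n, I, K))
  with_seed(derive_seed(spec$seed, "scoreblock"), {
    for (i in seq_len(I)) {
      hit <- runif(n) < spec$reliability[cbind(i, labels)]
      winner <- ifelse(hit, labels, spec$confusion[cbind(i, labels)])
      z <- matrix(rnorm(n * K, sd = spec$jitter), n, K)
      z[cbind(seq_len(n), winner)] <- apply(z, 1L, max) + 1 + abs(rnorm(n))
      arr[, i, ] <- softmax_rows(z / spec$temperature)
    }
  })
  block <- structure(list(scores = arr, sequence_ids = ids,
                          model_ids = sprintf("M%02d", seq_len(I)),
                          method = "synthetic"),
                     class = "etpfam_score_block")
  list(block = block, labels = tibble(sequence_id = ids, class = labels))
}
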