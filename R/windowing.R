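#' Windowing parameters
#'
#' Base classifiers see fixed-length windows of the embedding track: sampled
#' at random positions during training, slid with a discrete step at
#' inference time.
#'
#' @param W Window length in residues.
#' @param step Slide stride at inference (residues). Default 4.
#' @param n_per_seq Windows sampled per sequence per training epoch.
#'   Default 1.
#'
#' @return A `window_spec` list.
#' @export
window_spec <- function(W, step = 4L, n_per_seq = 1L) {
  stopifnot_scalar_int(W, "W")
  stopifnot_scalar_int(step, "step")
  stopifnot_scalar_int(n_per_seq, "n_per_seq")
  structure(list(W = as.integer(W), step = as.integer(step),
                 n_per_seq = as.integer(n_per_seq)),
            class = "window_spec")
}

# A window is a list(sequence_id, nb, ne, nc, slice, mask, label).
# nb: 0-based inclusive start; ne: 0-based exclusive end (before padding
# ne - nb may be < W; slice/mask are always width W);
# nc = nb + floor(W/2) is the centre coordinate; label is a class index or NA.
new_window <- function(sequence_id, nb, ne, slice, mask, label = NA_integer_) {
  list(sequence_id = sequence_id,
       nb = as.integer(nb), ne = as.integer(ne),
       nc = as.integer(nb + ncol(slice) %/% 2L),
       slice = slice, mask = mask, label = as.integer(label))
}

#' Right-pad a window slice to the full window width
#'
#' Slices shorter than `W` (sequences shorter than the window) are padded
#' with zero columns; the attached mask marks real columns so the
#' classifier's pooling can ignore the padding.
#'
#' @param slice An `E x w` matrix with `w <= W`.
#' @param W Target width.
#' @return A list with `slice` (`E x W`) and `mask` (logical length `W`).
#' @export
pad_window <- function(slice, W) {
  w <- ncol(slice)
  if (w > W) abort("Slice wider than the window length.")
  if (w == W) return(list(slice = slice, mask = rep(TRUE, W)))
  out <- matrix(0, nrow = nrow(slice), ncol = W)
  out[, seq_len(w)] <- slice
  list(slice = out, mask = c(rep(TRUE, w), rep(FALSE, W - w)))
}

# Valid 0-based training starts: windows overlapping some annotated domain
# by at least min(ceiling(W/2), domain length). Returns integer vector.
valid_training_starts <- function(L, W, domains) {
  if (L < W) return(0L)
  starts <- 0:(L - W)
  ok <- rep(FALSE, length(starts))
  for (j in seq_len(nrow(domains))) {
    ds <- domains$start[j] - 1L   # to 0-based half-open
    de <- domains$end[j]
    dlen <- de - ds
    need <- min(ceiling(W / 2), dlen)
    ov <- pmin(starts + W, de) - pmax(starts, ds)
    ok <- ok | (ov >= need)
  }
  starts[ok]
}

# Label of a window [nb, nb+W): family class of the maximal-overlap domain,
# ties broken by leftmost domain.
window_label <- function(nb, W, domains) {
  ov <- pmin(nb + W, domains$end) - pmax(nb, domains$start - 1L)
  best <- which.max(ov)  # leftmost on ties when rows are span-ordered
  domains$class[best]
}

#' Sample labeled training windows from one embedded sequence
#'
#' Window starts are drawn uniformly from the positions whose window
#' overlaps an annotated domain by at least half the window (or the whole
#' domain, if the domain is shorter than that). Each window is labeled with
#' the family of its maximal-overlap domain (ties: leftmost domain).
#' Sequences shorter than the window yield a single zero-padded, masked
#' window.
#'
#' @param emb An [embedded_sequence()] with a non-empty `domains` table.
#' @param spec A [window_spec()]; `spec$n_per_seq` windows are drawn.
#' @param seed Integer seed; identical seeds reproduce the windows exactly.
#'
#' @return A list of `spec$n_per_seq` labeled windows.
#' @export
sample_training_windows <- function(emb, spec, seed) {
  stopifnot(inherits(emb, "embedded_sequence"), inherits(spec, "window_spec"))
  domains <- emb$domains
  if (is.null(domains) || nrow(domains) == 0L) {
    abort(sprintf("Sequence '%s' has no domain annotation; %s",
                  emb$id, "training windows need labels."))
  }
  domains <- dplyr::arrange(domains, .data$start, .data$end)
  L <- ncol(emb$matrix)
  W <- spec$W
  starts <- valid_training_starts(L, W, domains)
  if (!length(starts)) {
    abort(sprintf("No valid training window position in sequence '%s'.",
                  emb$id))
  }
  picks <- with_seed(derive_seed(seed, "win", emb$id),
                     starts[sample.int(length(starts), spec$n_per_seq,
                                       replace = TRUE)])
  lapply(picks, function(nb) {
    ne <- min(nb + W, L)
    padded <- pad_window(emb$matrix[, (nb + 1L):ne, drop = FALSE], W)
    new_window(emb$id, nb, ne, padded$slice, padded$mask,
               label = window_label(nb, W, domains))
  })
}

#' Slide windows along an embedded sequence
#'
#' Starts are `0, step, 2*step, ...` while the window fits; a final
#' flush-right window ending at the last residue is appended when the
#' C-terminus would otherwise be uncovered, so every residue is scored.
#' Sequences shorter than `W` yield one zero-padded window.
#'
#' @param emb An [embedded_sequence()].
#' @param spec A [window_spec()].
#'
#' @return An ordered list of unlabeled windows.
#' @export
slide_windows <- function(emb, spec) {
  stopifnot(inherits(emb, "embedded_sequence"), inherits(spec, "window_spec"))
  L <- ncol(emb$matrix)
  W <- spec$W
  if (L < W) {
    padded <- pad_window(emb$matrix, W)
    return(list(new_window(emb$id, 0L, L, padded$slice, padded$mask)))
  }
  starts <- seq.int(0L, L - W, by = spec$step)
  if (tail(starts, 1L) != L - W) starts <- c(starts, L - W)
  lapply(starts, function(nb) {
    new_window(emb$id, nb, nb + W,
               emb$matrix[, (nb + 1L):(nb + W), drop = FALSE],
               rep(TRUE, W))
  })
}
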