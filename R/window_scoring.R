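#' Per-position class scores of one model on one sequence
#'
#' Stores the class-score vector emitted at each evaluated window centre
#' along a sequence. Tracks are the bridge between base models and the
#' per-sequence aggregation rules.
#'
#' @param sequence_id,model_id Identifiers.
#' @param positions Integer vector of window-centre residue indices
#'   (0-based), strictly increasing.
#' @param scores A `P x K` matrix, one probability row per position (each row
#'   sums to 1).
#' @param seq_length Residue count `L` of the sequence (used by the
#'   central-window rule).
#'
#' @return A `position_score_track` object.
#' @export
position_score_track <- function(sequence_id, model_id, positions, scores,
                                 seq_length) {
  scores <- as.matrix(scores)
  positions <- as.integer(positions)
  if (length(positions) < 1L) abort("A track needs at least one position.")
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("Track positions must be strictly increasing.")
  }
  if (nrow(scores) != length(positions)) {
    abort("One score row per position is required.")
  }
  if (any(abs(rowSums(scores) - 1) > 1e-6)) {
    abort("Each track score row must sum to 1 (softmax output).")
  }
  structure(list(sequence_id = sequence_id, model_id = model_id,
                 positions = positions, scores = scores,
                 seq_length = as.integer(seq_length)),
            class = "position_score_track")
}

#' @export
print.position_score_track <- function(x, ...) {
  cat(sprintf("<position_score_track> %s / %s: %d positions, K=%d, L=%d\n",
              x$sequence_id, x$model_id, length(x$positions),
              ncol(x$scores), x$seq_length))
  invisible(x)
}

#' Tidy a position score track into long format
#' @param x A [position_score_track()].
#' @param ... Unused.
#' @export
tidy.position_score_track <- function(x, ...) {
  tibble(sequence_id = x$sequence_id, model_id = x$model_id,
         position = rep(x$positions, times = ncol(x$scores)),
         class = rep(seq_len(ncol(x$scores)), each = length(x$positions)),
         score = as.vector(x$scores))
}

new_aggregated <- function(track, method, s) {
  list(sequence_id = track$sequence_id, model_id = track$model_id,
       method = method, s = as.vector(s), kappa = predict_class(s))
}

#' Predicted class from a score vector
#'
#' The lowest index attaining the maximum score (deterministic tie rule).
#'
#' @param s A finite numeric score vector over the classes.
#' @return An integer class index.
#' @export
predict_class <- function(s) {
  if (any(!is.finite(s))) abort("Scores must be finite.")
  which.max(s)
}

#' Collapse a score track into one per-sequence score vector
#'
#' Three rules turn the per-position scores `s_ik(n)` of one model on one
#' sequence into a single class-score vector `s_ik`:
#'
#' * **CwS** (central window score): the score row whose window centre lies
#'   nearest the sequence midpoint (ties: the earlier position).
#' * **SwA** (sliding window area): the mean score vector over all evaluated
#'   positions — the (normalized) area under each class's score curve.
#' * **SwC** (sliding window coverage): the fraction of evaluated positions
#'   at which each class had the winning score.
#'
#' All three return probability vectors; the per-model prediction is the
#' argmax (lowest index on ties).
#'
#' @param track A [position_score_track()].
#' @return A list with `sequence_id`, `model_id`, `method`, `s` (K-vector)
#'   and `kappa` (predicted class index).
#' @name window_scoring
NULL

#' @rdname window_scoring
#' @export
central_window_score <- function(track) {
  stopifnot(inherits(track, "position_score_track"))
  mid <- (track$seq_length - 1) / 2
  d <- abs(track$positions - mid)
  pick <- which.min(d)  # earlier position on ties
  new_aggregated(track, "cws", track$scores[pick, ])
}

#' @rdname window_scoring
#' @export
sliding_window_area <- function(track) {
  stopifnot(inherits(track, "position_score_track"))
  new_aggregated(track, "swa", colMeans(track$scores))
}

#' @rdname window_scoring
#' @export
sliding_window_coverage <- function(track) {
  stopifnot(inherits(track, "position_score_track"))
  winners <- apply(track$scores, 1L, which.max)
  s <- tabulate(winners, nbins = ncol(track$scores)) / length(winners)
  new_aggregated(track, "swc", s)
}

#' Aggregate many tracks into a tidy score table
#'
#' @param tracks A list of [position_score_track()] objects.
#' @param method One of `"cws"`, `"swa"`, `"swc"`.
#' @return A tibble with columns `sequence_id`, `model_id`, `method`,
#'   `kappa` (predicted class) and `s` (list-column of K-vectors).
#' @export
aggregate_tracks <- function(tracks, method = c("swc", "swa", "cws")) {
  method <- match.arg(method)
  fn <- switch(method,
               cws = central_window_score,
               swa = sliding_window_area,
               swc = sliding_window_coverage)
  rows <- lapply(tracks, fn)
  tibble(
    sequence_id = vapply(rows, `[[`, character(1), "sequence_id"),
    model_id = vapply(rows, `[[`, character(1), "model_id"),
    method = method,
    kappa = vapply(rows, `[[`, integer(1), "kappa"),
    s = lapply(rows, `[[`, "s")
  )
}
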