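#' Labels of one partition, ready for evaluation
#'
#' One row per annotated domain; `is_primary` marks the first-listed domain
#' of each sequence (used to attribute false negatives for multi-domain
#' proteins).
#'
#' @param split An [dataset_split()].
#' @param partition `"train"`, `"dev"` or `"test"`.
#' @return A tibble with `sequence_id`, `family`, `class`, `is_primary`.
#' @export
partition_labels <- function(split, partition) {
  split_partition(split, partition) |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(is_primary = dplyr::row_number() == 1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(sequence_id = .data$id, family = .data$family,
                     class = .data$class, is_primary = .data$is_primary)
}

# predictions: tibble(sequence_id, class); labels: tibble(sequence_id,
# class[, is_primary]). Returns per-sequence join with correctness under the
# any-annotated-family rule.
match_predictions <- function(predictions, labels) {
  if (!all(c("sequence_id", "class") %in% names(predictions))) {
    abort("`predictions` needs columns sequence_id and class.")
  }
  if (!"is_primary" %in% names(labels)) {
    labels <- labels |>
      dplyr::group_by(.data$sequence_id) |>
      dplyr::mutate(is_primary = dplyr::row_number() == 1L) |>
      dplyr::ungroup()
  }
  pred_ids <- predictions$sequence_id
  lab_ids <- unique(labels$sequence_id)
  if (anyDuplicated(pred_ids)) abort("One prediction per sequence, please.")
  if (!setequal(pred_ids, lab_ids)) {
    abort("Prediction and label sequence ids do not match.")
  }
  truth <- base::split(labels$class, labels$sequence_id)
  primary <- labels$class[labels$is_primary][
    match(pred_ids, labels$sequence_id[labels$is_primary])]
  tibble(
    sequence_id = pred_ids,
    predicted = as.integer(predictions$class),
    primary = as.integer(primary),
    correct = mapply(function(p, id) p %in% truth[[id]],
                     predictions$class, pred_ids)
  )
}

#' Overall (micro) error rate
#'
#' The pooled error `e = 1 - TP / (TP + FN)` over all test sequences. In
#' this single-prediction-per-sequence setting it equals the misclassified
#' fraction. A multi-domain sequence counts as correct when the predicted
#' family matches any of its annotated families.
#'
#' @param predictions Tibble with `sequence_id` and predicted `class` (or a
#'   named integer vector of class indices).
#' @param labels Label tibble ([partition_labels()]).
#' @return The error rate in `[0, 1]`.
#' @export
error_rate <- function(predictions, labels) {
  predictions <- as_prediction_tbl(predictions)
  m <- match_predictions(predictions, labels)
  1 - mean(m$correct)
}

as_prediction_tbl <- function(predictions) {
  if (is.data.frame(predictions)) return(predictions)
  if (is.null(names(predictions))) {
    abort("Vector predictions must be named by sequence_id.")
  }
  tibble(sequence_id = names(predictions), class = as.integer(predictions))
}

#' Per-family metrics table
#'
#' Per family: true positives, false positives, false negatives, recall
#' `r = TP / (TP + FN)`, error `e = 1 - r`, and `F1 = 2TP / (2TP + FP + FN)`
#' (0 when the denominator is 0 for a family with test members). The macro
#' mean F1 runs over families with at least one test member.
#'
#' @inheritParams error_rate
#' @param family_index Optional family index tibble (`family`, `class`) so
#'   families are reported by accession; defaults to bare class indices.
#' @param n_train Optional named count of training sequences per family
#'   (names = family), carried into the table for size-binned analyses.
#'
#' @return An `etpfam_metrics` object: list with `per_family` (tibble),
#'   `micro_error`, `macro_f1`, `n_test`.
#' @export
f1_table <- function(predictions, labels, family_index = NULL,
                     n_train = NULL) {
  predictions <- as_prediction_tbl(predictions)
  m <- match_predictions(predictions, labels)
  K <- max(c(m$predicted, labels$class))
  if (!is.null(family_index)) K <- max(K, family_index$class)
  tp <- integer(K); fp <- integer(K); fn <- integer(K); nt <- integer(K)
  for (r in seq_len(nrow(m))) {
    if (m$correct[r]) {
      tp[m$predicted[r]] <- tp[m$predicted[r]] + 1L
      nt[m$predicted[r]] <- nt[m$predicted[r]] + 1L
    } else {
      fp[m$predicted[r]] <- fp[m$predicted[r]] + 1L
      fn[m$primary[r]] <- fn[m$primary[r]] + 1L
      nt[m$primary[r]] <- nt[m$primary[r]] + 1L
    }
  }
  fam <- if (!is.null(family_index)) {
    family_index$family[order(family_index$class)][seq_len(K)]
  } else {
    sprintf("class_%d", seq_len(K))
  }
  per_family <- tibble(
    family = fam, class = seq_len(K),
    TP = tp, FP = fp, FN = fn, n_test = nt,
    recall = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
    error = ifelse(tp + fn > 0, 1 - tp / (tp + fn), NA_real_),
    f1 = ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  )
  if (!is.null(n_train)) {
    per_family$n_train <- as.integer(n_train[per_family$family])
    per_family$n_train[is.na(per_family$n_train)] <- 0L
  }
  structure(
    list(per_family = per_family,
         micro_error = 1 - mean(m$correct),
         macro_f1 = mean(per_family$f1[per_family$n_test > 0]),
         n_test = nrow(m)),
    class = "etpfam_metrics")
}

#' @export
print.etpfam_metrics <- function(x, ...) {
  cat(sprintf("<etpfam_metrics> %d test sequences: micro error %.4f, macro F1 %.4f\n",
              x$n_test, x$micro_error, x$macro_f1))
  invisible(x)
}

#' @export
tidy.etpfam_metrics <- function(x, ...) x$per_family

#' @export
glance.etpfam_metrics <- function(x, ...) {
  tibble(n_test = x$n_test, micro_error = x$micro_error,
         macro_f1 = x$macro_f1,
         n_families_with_test = sum(x$per_family$n_test > 0))
}

#' Families rescued by a second model
#'
#' Lists the families predicted with 100% error by model `a` but 0% error by
#' model `b` — the per-family mechanism by which a learned per-family
#' ensemble recovers families a single model gets entirely wrong.
#'
#' @param metrics_a,metrics_b `etpfam_metrics` over the same family universe.
#' @return A list with `families` (character), `n_full_error_a` (families at
#'   100% error under `a`) and `n_rescued`.
#' @export
rescue_analysis <- function(metrics_a, metrics_b) {
  a <- metrics_a$per_family
  b <- metrics_b$per_family
  if (!identical(a$family, b$family)) {
    abort("Metrics must share one family universe.")
  }
  full_a <- !is.na(a$error) & a$error == 1
  zero_b <- !is.na(b$error) & b$error == 0
  list(families = a$family[full_a & zero_b],
       n_full_error_a = sum(full_a),
       n_rescued = sum(full_a & zero_b))
}

#' Shared k-mer similarity between two sequences
#'
#' Jaccard index of the k-mer sets of the two residue strings — a cheap,
#' alignment-free stand-in for alignment-based identity. Any function with
#' the same signature can be plugged into [family_similarity()].
#'
#' @param a,b Residue strings.
#' @param k k-mer length (default 3).
#' @return Similarity in `[0, 1]`.
#' @export
kmer_similarity <- function(a, b, k = 3L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  ka <- kmers(a); kb <- kmers(b)
  if (!length(ka) || !length(kb)) return(0)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Test-to-train similarity of each family
#'
#' For every test protein of a family, the maximum similarity to any
#' training protein is retained; the family's similarity is the mean of
#' those per-protein maxima.
#'
#' @param train_sequences,test_sequences Sequence tibbles ([read_fasta()]).
#' @param train_labels,test_labels Label tibbles (`sequence_id`, `family`).
#' @param similarity_fn Pairwise similarity function (default
#'   [kmer_similarity()]).
#' @return A tibble with `family` and `similarity`.
#' @export
family_similarity <- function(train_sequences, test_sequences,
                              train_labels, test_labels,
                              similarity_fn = kmer_similarity) {
  train_res <- train_sequences$residues[
    match(train_labels$sequence_id, train_sequences$id)]
  fams <- unique(test_labels$family)
  out <- lapply(fams, function(f) {
    test_ids <- test_labels$sequence_id[test_labels$family == f]
    test_res <- test_sequences$residues[match(test_ids, test_sequences$id)]
    maxima <- vapply(test_res, function(ts) {
      if (!length(train_res)) return(0)
      max(vapply(train_res, function(tr) similarity_fn(ts, tr), numeric(1)))
    }, numeric(1))
    tibble(family = f, similarity = mean(maxima))
  })
  dplyr::bind_rows(out)
}

#' Mean F1 binned by a family-level key
#'
#' Orders families by training-set size or test-to-train similarity and
#' reports the mean F1 per bin, mirroring the performance-versus-family-size
#' and performance-versus-homology analyses.
#'
#' @param metrics An `etpfam_metrics` (only families with test members are
#'   binned).
#' @param key `"train_family_size"` (needs `n_train` in the table, see
#'   [f1_table()]) or `"test_to_train_similarity"`.
#' @param similarity Tibble from [family_similarity()] (required for the
#'   similarity key).
#' @param n_bins Number of equal-count bins.
#' @return A tibble with `bin`, `key_mean`, `mean_f1`, `n_families`.
#' @export
binned_performance <- function(metrics,
                               key = c("train_family_size",
                                       "test_to_train_similarity"),
                               similarity = NULL, n_bins = 5L) {
  key <- match.arg(key)
  tbl <- dplyr::filter(metrics$per_family, .data$n_test > 0)
  if (key == "train_family_size") {
    if (!"n_train" %in% names(tbl)) {
      abort("Pass `n_train` to f1_table() to bin by training family size.")
    }
    tbl$key_value <- tbl$n_train
  } else {
    if (is.null(similarity)) {
      abort("Binning by similarity needs the family_similarity() table.")
    }
    tbl$key_value <- similarity$similarity[match(tbl$family,
                                                 similarity$family)]
  }
  tbl <- dplyr::arrange(tbl, .data$key_value)
  tbl$bin <- dplyr::ntile(seq_len(nrow(tbl)), min(n_bins, nrow(tbl)))
  tbl |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(key_mean = mean(.data$key_value),
                     mean_f1 = mean(.data$f1),
                     n_families = dplyr::n(), .groups = "drop")
}
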