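#' Run the full pipeline end-to-end on a synthetic benchmark
#'
#' Generates a desk-scale synthetic benchmark, trains one small base model
#' per requested window length, scores every dev and test sequence by
#' sliding windows, aggregates the tracks (SwC for predictions, CwS for the
#' member-eligibility statistic), fits the requested ensemble combiner on
#' the development partition, evaluates everything on the test partition,
#' and writes the whole artifact chain (FASTA, split, embedding store,
#' per-model histories, prediction TSV, summary JSON) under `out_dir`.
#' Deterministic: the same seed reproduces every file byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param windows Window lengths, one base model each (default 8, 16, 32).
#' @param strategy Ensemble strategy (default `"lwf_perceptron"`;
#'   `"simple"` and `"score"` need no fitting).
#' @param bench_spec Optional [benchmark_spec()]; defaults to the standard
#'   small benchmark (K = 12, E = 16, 300 sequences) reseeded from `seed`.
#' @param F,Fb,lr,n_per_seq,max_epochs,batch_size Small-scale training
#'   settings shared by all base models.
#' @param quiet Suppress per-stage messages.
#'
#' @return Invisibly, the summary list (also written as `summary.json`):
#'   per-model dev/test errors, the ensemble test error, and file paths.
#' @export
run_demo <- function(out_dir = tempfile("etpfam_demo_"), seed = 1L,
                     windows = c(8L, 16L, 32L),
                     strategy = "lwf_perceptron",
                     bench_spec = NULL,
                     F = 32L, Fb = 16L, lr = 1e-3, n_per_seq = 4L,
                     max_epochs = 30L, batch_size = 64L, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("[synth] generating benchmark")
  bspec <- bench_spec %||% benchmark_spec(seed = derive_seed(seed, "bench"))
  bench <- generate_benchmark(bspec, out_dir = out_dir)
  split <- bench$split
  parts <- lapply(c(train = "train", dev = "dev", test = "test"),
                  function(p) {
                    ids <- unique(split_partition(split, p)$id)
                    bench$embedded[ids]
                  })
  K <- nrow(split$family_index)
  E <- bspec$embed_dim

  say("[train-base] %d base models (W = %s)", length(windows),
      paste(windows, collapse = ", "))
  models <- lapply(windows, function(W) {
    cfg <- base_model_config(
      W = W, E = E, K = K, F = F, Fb = Fb, lr = lr,
      seed = derive_seed(seed, "model", W),
      n_per_seq = n_per_seq, max_epochs = max_epochs,
      batch_size = batch_size)
    m <- train_base_model(build_base_model(cfg), parts$train, parts$dev)
    say("[train-base] %s: best epoch %d, dev window error %.3f",
        cfg$model_id, m$best_epoch,
        m$history$dev_error[m$best_epoch])
    m
  })

  say("[score] sliding windows over dev and test")
  score_part <- function(set) {
    unlist(lapply(models, function(m) {
      lapply(set, function(e) score_sequence(m, e))
    }), recursive = FALSE)
  }
  dev_tracks <- score_part(parts$dev)
  test_tracks <- score_part(parts$test)

  say("[aggregate] CwS + SwC")
  agg <- list(
    dev_swc = aggregate_tracks(dev_tracks, "swc"),
    dev_cws = aggregate_tracks(dev_tracks, "cws"),
    test_swc = aggregate_tracks(test_tracks, "swc")
  )
  dev_labels_all <- partition_labels(split, "dev")
  test_labels <- partition_labels(split, "test")
  dev_primary <- dplyr::filter(dev_labels_all, .data$is_primary)

  model_ids <- vapply(models, function(m) m$config$model_id, character(1))
  per_model <- dplyr::bind_rows(lapply(models, glance)) |>
    dplyr::mutate(
      dev_error_cws = vapply(model_ids, function(mid) {
        error_rate(pred_of(agg$dev_cws, mid), dev_labels_all)
      }, numeric(1), USE.NAMES = FALSE),
      dev_error_swc = vapply(model_ids, function(mid) {
        error_rate(pred_of(agg$dev_swc, mid), dev_labels_all)
      }, numeric(1), USE.NAMES = FALSE),
      test_error_swc = vapply(model_ids, function(mid) {
        error_rate(pred_of(agg$test_swc, mid), test_labels)
      }, numeric(1), USE.NAMES = FALSE)
    )

  say("[fit-ensemble] %s on the development partition", strategy)
  dev_block <- score_block(agg$dev_swc, model_ids = model_ids)
  test_block <- score_block(agg$test_swc, model_ids = model_ids)
  if (strategy %in% c("simple", "score")) {
    combiner <- NULL
    ens_pred <- ensemble_predict(test_block, strategy)
  } else {
    combiner <- fit_combiner(strategy, dev_block, dev_primary,
                             seed = derive_seed(seed, "combiner"))
    ens_pred <- predict(combiner, test_block)
  }

  say("[evaluate] test partition")
  ens_error <- error_rate(ens_pred, test_labels)
  conf <- if (!is.null(combiner)) {
    softmax_rows(combiner_logits(combiner, test_block$scores))
  }
  pred_tbl <- tibble(
    sequence_id = test_block$sequence_ids,
    predicted_family = split$family_index$family[ens_pred],
    score = if (is.null(conf)) {
      apply(apply(test_block$scores, c(1L, 3L), mean), 1L, max)
    } else {
      conf[cbind(seq_along(ens_pred), ens_pred)]
    }
  )
  readr::write_tsv(pred_tbl, file.path(out_dir, "predictions.tsv"))

  summary <- list(
    seed = seed,
    benchmark = list(n_sequences = bspec$n_sequences, n_families = K,
                     embed_dim = E),
    models = lapply(seq_along(models), function(j) {
      list(model_id = model_ids[j], W = models[[j]]$config$W,
           best_epoch = models[[j]]$best_epoch,
           dev_error_cws = per_model$dev_error_cws[j],
           dev_error_swc = per_model$dev_error_swc[j],
           test_error_swc = per_model$test_error_swc[j])
    }),
    ensemble = list(strategy = strategy, aggregation = "swc",
                    test_error = ens_error,
                    best_base_test_error = min(per_model$test_error_swc))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("[done] ensemble test error %.4f vs best base %.4f (%.1f s)",
      ens_error, min(per_model$test_error_swc),
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(c(summary, list(out_dir = out_dir, per_model = per_model,
                            combiner = combiner, models = models)))
}

# Predictions of one model from an aggregated score table.
pred_of <- function(agg, model_id) {
  sub <- agg[agg$model_id == model_id, ]
  setNames(sub$kappa, sub$sequence_id)
}
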