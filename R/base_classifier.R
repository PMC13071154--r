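#' Configuration of one base window classifier
#'
#' Each base model is a residual bottleneck convolutional network applied to
#' fixed-length windows of the embedding track: an entry kernel-1
#' convolution into `F` filters, a bottleneck branch (kernel-3 conv to `Fb`
#' filters, ReLU, kernel-3 conv back to `F`) added to the skip path, ReLU, a
#' masked max-pool along the window, and a linear layer over the `K`
#' families. Trained with softmax cross-entropy and Adam, early-stopped on
#' development loss.
#'
#' @param W Window length (residues).
#' @param E Embedding dimension of the input tracks.
#' @param K Number of family classes.
#' @param F Filter count of the first and last convolutions (default 1100,
#'   the full-scale setting; use much smaller values at desk scale).
#' @param Fb Bottleneck filter count (default 550).
#' @param lr Adam learning rate (full-scale grid: 1e-4, 1e-5, 1e-6).
#' @param seed Integer seed fixing initialization and window sampling.
#' @param patience Epochs without development improvement before stopping.
#' @param max_epochs Epoch budget.
#' @param batch_size Minibatch size.
#' @param n_per_seq Training windows sampled per sequence per epoch.
#' @param step Inference slide stride.
#' @param model_id Identifier used in score tables; defaults to a readable
#'   summary of `(W, lr, seed)`.
#'
#' @return A `base_model_config` list.
#' @export
base_model_config <- function(W, E, K, F = 1100L, Fb = 550L, lr = 1e-4,
                              seed = 1L, patience = 5L, max_epochs = 50L,
                              batch_size = 256L, n_per_seq = 1L, step = 4L,
                              model_id = NULL) {
  stopifnot(F >= Fb, Fb >= 1L, lr > 0, patience >= 1L)
  model_id <- model_id %||% sprintf("W%d_lr%g_s%d", W, lr, seed)
  structure(list(W = as.integer(W), E = as.integer(E), K = as.integer(K),
                 F = as.integer(F), Fb = as.integer(Fb), lr = lr,
                 seed = as.integer(seed), patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 n_per_seq = as.integer(n_per_seq), step = as.integer(step),
                 model_id = model_id),
            class = "base_model_config")
}

#' Build an untrained base model
#'
#' @param config A [base_model_config()].
#' @return An `etpfam_base_model` with seeded initial parameters.
#' @export
build_base_model <- function(config) {
  stopifnot(inherits(config, "base_model_config"))
  params <- nn_init_params(config$E, config$W, config$F, config$Fb,
                           config$K, config$seed)
  structure(list(config = config, params = params, trained = FALSE,
                 history = NULL, best_epoch = NA_integer_),
            class = "etpfam_base_model")
}

#' @export
print.etpfam_base_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<etpfam_base_model> %s: W=%d E=%d K=%d F=%d Fb=%d (%s)\n",
              cfg$model_id, cfg$W, cfg$E, cfg$K, cfg$F, cfg$Fb,
              if (x$trained) sprintf("trained, best epoch %d", x$best_epoch)
              else "untrained"))
  invisible(x)
}

#' Score a single window
#'
#' @param model An `etpfam_base_model`.
#' @param window A window from [slide_windows()] or
#'   [sample_training_windows()].
#' @return A probability vector over the `K` classes (sums to 1).
#' @export
score_window <- function(model, window) {
  cfg <- model$config
  if (nrow(window$slice) != cfg$E || ncol(window$slice) != cfg$W) {
    abort(sprintf("Window slice is %dx%d but the model expects %dx%d.",
                  nrow(window$slice), ncol(window$slice), cfg$E, cfg$W))
  }
  drop(score_window_batch(model, list(window)))
}

# Batched scoring: list of windows -> B x K probability matrix.
score_window_batch <- function(model, windows) {
  batch <- nn_batch(windows)
  out <- nn_forward(model$params, batch$X, batch$W, batch$B, batch$mask,
                    keep_cache = FALSE)
  t(softmax_cols(out$logits))
}

#' Early-stopping controller
#'
#' Tracks a to-be-minimized metric; training stops after `patience`
#' consecutive epochs without strict improvement, and the best epoch's
#' parameters are the ones kept.
#'
#' @param patience Consecutive non-improving epochs tolerated.
#' @return An `early_stopper` state list.
#' @export
early_stopper <- function(patience = 5L) {
  list(patience = as.integer(patience), best = Inf,
       best_epoch = NA_integer_, bad = 0L, stop = FALSE, epoch = 0L)
}

#' @rdname early_stopper
#' @param state An `early_stopper` state.
#' @param metric The epoch's development metric (lower is better).
#' @return Updated state; fields `improved`, `stop`, `best_epoch`.
#' @export
early_stopper_update <- function(state, metric) {
  state$epoch <- state$epoch + 1L
  improved <- metric < state$best
  if (improved) {
    state$best <- metric
    state$best_epoch <- state$epoch
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (state$bad >= state$patience) state$stop <- TRUE
  }
  state$improved <- improved
  state
}

# Deterministic dev evaluation set: one labeled window per dev sequence,
# fixed across epochs.
dev_window_set <- function(dev_set, spec, seed) {
  unlist(lapply(dev_set, function(e) {
    sample_training_windows(e, spec, seed = derive_seed(seed, "devwin"))
  }), recursive = FALSE)
}

eval_windows <- function(params, windows, batch_size = 512L) {
  n <- length(windows)
  losses <- numeric(0)
  errs <- logical(0)
  for (i in seq(1L, n, by = batch_size)) {
    batch <- nn_batch(windows[i:min(i + batch_size - 1L, n)])
    out <- nn_forward(params, batch$X, batch$W, batch$B, batch$mask,
                      keep_cache = FALSE)
    ce <- nn_softmax_ce(out$logits, batch$y)
    losses <- c(losses, ce$loss * batch$B)
    errs <- c(errs, apply(out$logits, 2L, which.max) != batch$y)
  }
  list(loss = sum(losses) / n, error = mean(errs))
}

#' Train a base model with early stopping
#'
#' Each epoch samples `n_per_seq` labeled windows from every training
#' sequence (a fresh draw per epoch, reproducible from the model seed),
#' optimizes softmax cross-entropy with Adam, then evaluates loss and window
#' error on a fixed development window set. Training stops when development
#' loss has not improved for `patience` epochs or at `max_epochs`; the
#' returned model carries the best epoch's parameters and the full history.
#'
#' @param model An untrained `etpfam_base_model` from [build_base_model()].
#' @param train_set,dev_set Named lists of [embedded_sequence()] objects with
#'   domain annotations (see [load_embeddings()]).
#'
#' @return The trained `etpfam_base_model`; `history` is a tibble with
#'   columns `epoch`, `train_loss`, `dev_loss`, `dev_error`.
#' @export
train_base_model <- function(model, train_set, dev_set) {
  cfg <- model$config
  if (length(train_set) == 0L) abort("Empty training set.")
  if (length(dev_set) == 0L) abort("Empty development set.")
  spec <- window_spec(cfg$W, step = cfg$step, n_per_seq = cfg$n_per_seq)
  dev_windows <- dev_window_set(dev_set, spec, cfg$seed)
  params <- model$params
  opt <- adam_init(params)
  es <- early_stopper(cfg$patience)
  best_params <- params
  history <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    wins <- unlist(lapply(train_set, function(e) {
      sample_training_windows(e, spec,
                              seed = derive_seed(cfg$seed, "epoch", epoch))
    }), recursive = FALSE)
    ord <- with_seed(derive_seed(cfg$seed, "shuffle", epoch),
                     sample.int(length(wins)))
    wins <- wins[ord]
    epoch_loss <- 0
    n_seen <- 0L
    for (i in seq(1L, length(wins), by = cfg$batch_size)) {
      batch <- nn_batch(wins[i:min(i + cfg$batch_size - 1L, length(wins))])
      fwd <- nn_forward(params, batch$X, batch$W, batch$B, batch$mask)
      ce <- nn_softmax_ce(fwd$logits, batch$y)
      grads <- nn_backward(params, fwd$cache, ce$dlogits)
      upd <- adam_step(params, grads, opt, cfg$lr)
      params <- upd$params
      opt <- upd$state
      epoch_loss <- epoch_loss + ce$loss * batch$B
      n_seen <- n_seen + batch$B
    }
    dev <- eval_windows(params, dev_windows)
    history[[epoch]] <- tibble(epoch = epoch,
                               train_loss = epoch_loss / n_seen,
                               dev_loss = dev$loss, dev_error = dev$error)
    es <- early_stopper_update(es, dev$loss)
    if (es$improved) best_params <- params
    if (es$stop) break
  }
  model$params <- best_params
  model$trained <- TRUE
  model$best_epoch <- es$best_epoch
  model$history <- dplyr::bind_rows(history[!vapply(history, is.null,
                                                    logical(1))])
  model
}

#' Score every slide position of a sequence
#'
#' Applies the model at each sliding-window position (see [slide_windows()])
#' and collects the per-position class-score vectors.
#'
#' @param model A trained `etpfam_base_model`.
#' @param emb An [embedded_sequence()].
#' @param spec Optional [window_spec()]; defaults to the model's `W` and
#'   `step`.
#' @return A [position_score_track()].
#' @export
score_sequence <- function(model, emb, spec = NULL) {
  cfg <- model$config
  spec <- spec %||% window_spec(cfg$W, step = cfg$step)
  wins <- slide_windows(emb, spec)
  probs <- score_window_batch(model, wins)
  position_score_track(
    sequence_id = emb$id,
    model_id = cfg$model_id,
    positions = vapply(wins, function(w) w$nc, integer(1)),
    scores = probs,
    seq_length = ncol(emb$matrix)
  )
}

#' @export
tidy.etpfam_base_model <- function(x, ...) {
  x$history %||% tibble(epoch = integer(), train_loss = double(),
                        dev_loss = double(), dev_error = double())
}

#' @export
glance.etpfam_base_model <- function(x, ...) {
  h <- tidy(x)
  best <- h[h$epoch == x$best_epoch, ]
  tibble(model_id = x$config$model_id, W = x$config$W, lr = x$config$lr,
         seed = x$config$seed, epochs_run = nrow(h),
         best_epoch = x$best_epoch,
         dev_loss = if (nrow(best)) best$dev_loss else NA_real_,
         dev_error = if (nrow(best)) best$dev_error else NA_real_)
}

#' @export
autoplot.etpfam_base_model <- function(object, ...) {
  h <- tidy(object) |>
    tidyr::pivot_longer(c("train_loss", "dev_loss"),
                        names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(title = object$config$model_id,
                  x = "epoch", y = "cross-entropy loss", colour = NULL)
}
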