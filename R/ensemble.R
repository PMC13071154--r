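#' Assemble per-model aggregated scores into a score block
#'
#' A score block is the ensemble layer's input: the dense tensor
#' `s[sequence, model, class]` of aggregated per-sequence scores of `I` base
#' models over `K` classes. Every (sequence, model) pair must be present.
#'
#' @param agg An aggregated score tibble from [aggregate_tracks()] (single
#'   method), or any tibble with columns `sequence_id`, `model_id` and a
#'   list-column `s` of equal-length score vectors.
#' @param model_ids Optional model order; default sorted unique.
#' @param sequence_ids Optional sequence order; default sorted unique.
#'
#' @return An `etpfam_score_block`: list with `scores` (n x I x K array),
#'   `sequence_ids`, `model_ids`, `method`.
#' @export
score_block <- function(agg, model_ids = NULL, sequence_ids = NULL) {
  model_ids <- model_ids %||% sort(unique(agg$model_id))
  sequence_ids <- sequence_ids %||% sort(unique(agg$sequence_id))
  K <- length(agg$s[[1L]])
  n <- length(sequence_ids)
  I <- length(model_ids)
  arr <- array(NA_real_, dim = c(n, I, K))
  si <- match(agg$sequence_id, sequence_ids)
  mi <- match(agg$model_id, model_ids)
  for (r in seq_len(nrow(agg))) {
    if (is.na(si[r]) || is.na(mi[r])) next
    arr[si[r], mi[r], ] <- agg$s[[r]]
  }
  if (anyNA(arr)) {
    abort("Score block is incomplete: every (sequence, model) pair needs a score vector.")
  }
  method <- if ("method" %in% names(agg)) unique(agg$method) else "unknown"
  if (length(method) != 1L) {
    abort("Mixing aggregation methods in one score block is not allowed.")
  }
  structure(list(scores = arr, sequence_ids = sequence_ids,
                 model_ids = model_ids, method = method),
            class = "etpfam_score_block")
}

#' @export
print.etpfam_score_block <- function(x, ...) {
  d <- dim(x$scores)
  cat(sprintf("<etpfam_score_block> %d sequences x %d models x %d classes (%s)\n",
              d[1L], d[2L], d[3L], x$method))
  invisible(x)
}

block_dims <- function(block) {
  d <- dim(block$scores)
  list(n = d[1L], I = d[2L], K = d[3L])
}

# argmax per row with lowest-index tie rule.
row_argmax <- function(M) max.col(M, ties.method = "first")

# Per-model predicted classes: n x I integer matrix.
block_kappas <- function(block) {
  d <- block_dims(block)
  out <- matrix(0L, d$n, d$I)
  for (i in seq_len(d$I)) {
    out[, i] <- row_argmax(matrix(block$scores[, i, ], d$n, d$K))
  }
  out
}

#' Ensemble voting strategies
#'
#' Combine the per-model score vectors of a block into one predicted family
#' per sequence:
#'
#' * `simple_vote()`: each model casts one vote for its argmax class; the
#'   most voted class wins.
#' * `score_vote()`: the class with the maximum sum of scores over models
#'   wins.
#' * `lwm_predict()`: scores weighted per model, `argmax_k sum_i w_i s_ik`.
#' * `lwf_predict()`: per-model-per-family weights with per-family bias,
#'   `argmax_k sum_i w_ik s_ik + b_k`, or a per-family MLP `argmax_k f_k(s_k)`.
#' * `stack_predict()`: a second-stage classifier over the concatenation of
#'   all models' full score vectors.
#'
#' Ties are always broken by the lowest class index.
#'
#' @param block An [score_block()].
#' @return A named integer vector of predicted class indices, one per
#'   sequence.
#' @name ensemble_voting
NULL

#' @rdname ensemble_voting
#' @export
simple_vote <- function(block) {
  d <- block_dims(block)
  kap <- block_kappas(block)
  votes <- matrix(0L, d$n, d$K)
  for (i in seq_len(d$I)) {
    votes[cbind(seq_len(d$n), kap[, i])] <-
      votes[cbind(seq_len(d$n), kap[, i])] + 1L
  }
  setNames(row_argmax(votes), block$sequence_ids)
}

#' @rdname ensemble_voting
#' @export
score_vote <- function(block) {
  sums <- apply(block$scores, c(1L, 3L), sum)
  setNames(row_argmax(sums), block$sequence_ids)
}

#' @rdname ensemble_voting
#' @param w Numeric vector of per-model weights (length `I`).
#' @export
lwm_predict <- function(block, w) {
  d <- block_dims(block)
  if (length(w) != d$I) {
    abort(sprintf("Expected %d model weights, got %d.", d$I, length(w)))
  }
  logits <- combiner_logits(list(strategy = "lwm", params = list(w = w)),
                            block$scores)
  setNames(row_argmax(logits), block$sequence_ids)
}

#' @rdname ensemble_voting
#' @param combiner A fitted [fit_combiner()] result of the matching strategy.
#' @export
lwf_predict <- function(block, combiner) {
  if (!combiner$strategy %in% c("lwf_perceptron", "lwf_mlp")) {
    abort("`combiner` must be an lwf_perceptron or lwf_mlp combiner.")
  }
  predict(combiner, block)
}

#' @rdname ensemble_voting
#' @export
stack_predict <- function(block, combiner) {
  if (!combiner$strategy %in% c("stack_perceptron", "stack_mlp")) {
    abort("`combiner` must be a stack_perceptron or stack_mlp combiner.")
  }
  predict(combiner, block)
}

# ---- combiner parameterizations -------------------------------------------

ensemble_strategies <- function() {
  c("simple", "score", "lwm", "lwf_perceptron", "lwf_mlp",
    "stack_perceptron", "stack_mlp")
}

# Initial parameters. LWM/LWF start at the score-voting reduction
# (w = 1, b = 0); the LWF-MLP hidden layer is built as a +/- identity pair
# so its initial output also equals score voting (scores are non-negative);
# stacking starts from own-class block weights for the same reason. Classes
# never seen during fitting therefore keep score-voting behaviour.
combiner_init <- function(strategy, I, K, hidden, seed) {
  switch(
    strategy,
    lwm = list(w = rep(1, I)),
    lwf_perceptron = list(W = matrix(1, I, K), b = rep(0, K)),
    lwf_mlp = {
      H <- 2L * I
      A0 <- rbind(diag(1, I), diag(-1, I))  # H x I
      A <- array(rep(A0, K), dim = c(H, I, K))
      jit <- with_seed(derive_seed(seed, "lwfmlp"),
                       array(rnorm(H * I * K, sd = 0.01), dim = c(H, I, K)))
      list(A = A + jit, c = matrix(0, H, K),
           u = matrix(c(rep(1, I), rep(-1, I)), H, K), d = rep(0, K))
    },
    stack_perceptron = {
      Wt <- array(0, dim = c(I, K, K))
      for (k in seq_len(K)) Wt[, k, k] <- 1
      list(W = Wt, b = rep(0, K))
    },
    stack_mlp = {
      H <- hidden
      with_seed(derive_seed(seed, "stackmlp"), {
        list(W1 = matrix(rnorm(H * I * K, sd = sqrt(2 / (I * K))), H, I * K),
             b1 = rep(0, H),
             W2 = matrix(rnorm(K * H, sd = sqrt(2 / H)), K, H),
             b2 = rep(0, K))
      })
    },
    abort(sprintf("Strategy '%s' has no learnable parameters.", strategy))
  )
}

# Per-class logits (n x K) of a combiner on a score tensor S (n x I x K).
combiner_logits <- function(combiner, S) {
  d <- dim(S)
  n <- d[1L]; I <- d[2L]; K <- d[3L]
  p <- combiner$params
  switch(
    combiner$strategy,
    lwm = {
      logits <- matrix(0, n, K)
      for (k in seq_len(K)) {
        logits[, k] <- matrix(S[, , k], n, I) %*% p$w
      }
      logits
    },
    lwf_perceptron = {
      logits <- matrix(0, n, K)
      for (k in seq_len(K)) {
        logits[, k] <- matrix(S[, , k], n, I) %*% p$W[, k] + p$b[k]
      }
      logits
    },
    lwf_mlp = {
      logits <- matrix(0, n, K)
      for (k in seq_len(K)) {
        Sk <- matrix(S[, , k, drop = TRUE], n, I)
        Hk <- relu(Sk %*% t(p$A[, , k]) +
                     matrix(p$c[, k], n, nrow(p$A), byrow = TRUE))
        logits[, k] <- Hk %*% p$u[, k] + p$d[k]
      }
      logits
    },
    stack_perceptron = {
      X <- matrix(S, n, I * K)
      X %*% matrix(p$W, I * K, K) +
        matrix(p$b, n, K, byrow = TRUE)
    },
    stack_mlp = {
      X <- matrix(S, n, I * K)
      H1 <- relu(X %*% t(p$W1) + matrix(p$b1, n, length(p$b1), byrow = TRUE))
      H1 %*% t(p$W2) + matrix(p$b2, n, K, byrow = TRUE)
    },
    abort(sprintf("No logits for strategy '%s'.", combiner$strategy))
  )
}

# Parameter gradients from G = dLoss/dlogits (n x K).
combiner_grads <- function(combiner, S, G) {
  d <- dim(S)
  n <- d[1L]; I <- d[2L]; K <- d[3L]
  p <- combiner$params
  switch(
    combiner$strategy,
    lwm = {
      w <- rep(0, I)
      for (k in seq_len(K)) {
        w <- w + drop(t(matrix(S[, , k, drop = TRUE], n, I)) %*% G[, k])
      }
      list(w = w)
    },
    lwf_perceptron = {
      W <- matrix(0, I, K)
      for (k in seq_len(K)) {
        W[, k] <- drop(t(matrix(S[, , k, drop = TRUE], n, I)) %*% G[, k])
      }
      list(W = W, b = colSums(G))
    },
    lwf_mlp = {
      H <- nrow(p$A)
      gA <- array(0, dim = dim(p$A)); gc <- matrix(0, H, K)
      gu <- matrix(0, H, K); gd <- rep(0, K)
      for (k in seq_len(K)) {
        Sk <- matrix(S[, , k, drop = TRUE], n, I)
        pre <- Sk %*% t(p$A[, , k]) + matrix(p$c[, k], n, H, byrow = TRUE)
        Hk <- relu(pre)
        gk <- G[, k]
        gu[, k] <- drop(t(Hk) %*% gk)
        gd[k] <- sum(gk)
        dH <- (gk %o% p$u[, k]) * (pre > 0)   # n x H
        gA[, , k] <- t(dH) %*% Sk
        gc[, k] <- colSums(dH)
      }
      list(A = gA, c = gc, u = gu, d = gd)
    },
    stack_perceptron = {
      X <- matrix(S, n, I * K)
      list(W = array(t(X) %*% G, dim = dim(p$W)), b = colSums(G))
    },
    stack_mlp = {
      X <- matrix(S, n, I * K)
      pre <- X %*% t(p$W1) + matrix(p$b1, n, length(p$b1), byrow = TRUE)
      H1 <- relu(pre)
      gW2 <- t(G) %*% H1
      gb2 <- colSums(G)
      dH1 <- (G %*% p$W2) * (pre > 0)
      list(W1 = t(dH1) %*% X, b1 = colSums(dH1), W2 = gW2, b2 = gb2)
    }
  )
}

#' Fit a learned ensemble combiner on the development partition
#'
#' Learned strategies (`lwm`, `lwf_perceptron`, `lwf_mlp`,
#' `stack_perceptron`, `stack_mlp`) minimize softmax cross-entropy of their
#' per-class scores by full-batch gradient descent with adaptive-moment
#' (Adam) updates, after the base models are trained, using the base models'
#' aggregated development scores as input. A fraction of the development
#' rows is held out internally for the combiner's own early stopping.
#'
#' LWM and LWF start at the score-voting reduction (`w = 1`, `b = 0`), so
#' families that never occur in the development rows keep score-voting
#' behaviour.
#'
#' @param strategy One of the learned strategy names.
#' @param dev_block A [score_block()] of development sequences.
#' @param dev_labels Integer class per development sequence: either a vector
#'   aligned with `dev_block$sequence_ids` or a tibble with columns
#'   `sequence_id` and `class`.
#' @param seed Integer seed (holdout draw and any random initialization).
#' @param lr Adam learning rate.
#' @param max_iter Gradient-descent iteration budget.
#' @param patience Early-stopping patience on the held-out loss.
#' @param holdout_frac Fraction of dev rows held out for early stopping.
#' @param hidden Hidden width of the stacking MLP (default 256).
#'
#' @return An `etpfam_combiner` with the best-iteration parameters, the fit
#'   history, and `fit_meta` echoing the optimizer settings.
#' @export
fit_combiner <- function(strategy, dev_block, dev_labels, seed = 1L,
                         lr = 0.05, max_iter = 300L, patience = 5L,
                         holdout_frac = 0.1, hidden = 256L) {
  if (strategy %in% c("simple", "score")) {
    abort(sprintf("Strategy '%s' has nothing to fit.", strategy))
  }
  if (!strategy %in% ensemble_strategies()) {
    abort(sprintf("Unknown ensemble strategy '%s'.", strategy))
  }
  d <- block_dims(dev_block)
  y <- align_labels(dev_labels, dev_block$sequence_ids)
  if (strategy == "stack_perceptron" && d$I * d$K^2 > 5e7) {
    warn(sprintf(
      "stack_perceptron fits %d x %d x %d weights; this is intentionally huge and prone to overfitting.",
      d$I, d$K, d$K))
  }
  combiner <- structure(
    list(strategy = strategy,
         params = combiner_init(strategy, d$I, d$K, hidden, seed),
         n_models = d$I, n_classes = d$K, model_ids = dev_block$model_ids,
         trained = FALSE, history = NULL,
         fit_meta = list(seed = seed, lr = lr, max_iter = max_iter,
                         patience = patience, holdout_frac = holdout_frac)),
    class = "etpfam_combiner")
  n_hold <- max(1L, min(d$n - 1L, round(holdout_frac * d$n)))
  hold <- with_seed(derive_seed(seed, "holdout"),
                    sort(sample.int(d$n, n_hold)))
  tr <- setdiff(seq_len(d$n), hold)
  S_tr <- dev_block$scores[tr, , , drop = FALSE]
  S_ho <- dev_block$scores[hold, , , drop = FALSE]
  y_tr <- y[tr]; y_ho <- y[hold]
  params <- combiner$params
  opt <- adam_init(params)
  es <- early_stopper(patience)
  best <- params
  history <- vector("list", max_iter)
  for (it in seq_len(max_iter)) {
    combiner$params <- params
    logits <- combiner_logits(combiner, S_tr)
    ce <- nn_softmax_ce(t(logits), y_tr)
    grads <- combiner_grads(combiner, S_tr, t(ce$dlogits))
    upd <- adam_step(params, grads, opt, lr)
    params <- upd$params
    opt <- upd$state
    combiner$params <- params
    val <- nn_softmax_ce(t(combiner_logits(combiner, S_ho)), y_ho)$loss
    history[[it]] <- tibble(iter = it, train_loss = ce$loss, val_loss = val)
    es <- early_stopper_update(es, val)
    if (es$improved) best <- params
    if (es$stop) break
  }
  combiner$params <- best
  combiner$trained <- TRUE
  combiner$best_iter <- es$best_epoch
  combiner$history <- dplyr::bind_rows(
    history[!vapply(history, is.null, logical(1))])
  combiner
}

#' Build a combiner from hand-specified parameters
#'
#' Mostly useful for analysis and testing: lets you evaluate an ensemble
#' with explicitly chosen weights (e.g. per-class expert selection, or the
#' score-voting reductions `w = 1`, `b = 0`) without fitting.
#'
#' @param strategy A learned strategy name (see [fit_combiner()]).
#' @param params Parameter list with the strategy's shapes: `lwm`: `w`
#'   (length `I`); `lwf_perceptron`: `W` (`I x K`), `b` (length `K`);
#'   `stack_perceptron`: `W` (`I x K x K`, indexed model, input class,
#'   output class), `b`; `lwf_mlp` / `stack_mlp`: the fields produced by
#'   [fit_combiner()].
#' @param n_models,n_classes Block dimensions the combiner expects.
#' @param model_ids Optional model identifiers.
#' @return A trained-flagged `etpfam_combiner`.
#' @export
make_combiner <- function(strategy, params, n_models, n_classes,
                          model_ids = NULL) {
  if (!strategy %in% setdiff(ensemble_strategies(), c("simple", "score"))) {
    abort(sprintf("Strategy '%s' takes no parameters.", strategy))
  }
  structure(list(strategy = strategy, params = params,
                 n_models = as.integer(n_models),
                 n_classes = as.integer(n_classes),
                 model_ids = model_ids %||% sprintf("M%02d",
                                                    seq_len(n_models)),
                 trained = TRUE, history = NULL, fit_meta = list()),
            class = "etpfam_combiner")
}

align_labels <- function(labels, sequence_ids) {
  if (is.data.frame(labels)) {
    m <- match(sequence_ids, labels$sequence_id)
    if (anyNA(m)) abort("Labels missing for some block sequences.")
    as.integer(labels$class[m])
  } else {
    if (length(labels) != length(sequence_ids)) {
      abort("Label vector length must match the block's sequences.")
    }
    as.integer(labels)
  }
}

#' @export
print.etpfam_combiner <- function(x, ...) {
  cat(sprintf("<etpfam_combiner> %s: I=%d models, K=%d classes (%s)\n",
              x$strategy, x$n_models, x$n_classes,
              if (x$trained) "fitted" else "unfitted"))
  invisible(x)
}

#' Predict with a fitted combiner
#'
#' @param object An `etpfam_combiner`.
#' @param block An [score_block()] with the same models and classes the
#'   combiner was fitted on.
#' @param ... Unused.
#' @return Named integer vector of predicted class indices.
#' @export
predict.etpfam_combiner <- function(object, block, ...) {
  if (!object$trained) {
    abort("Combiner is unfitted; call fit_combiner() first.")
  }
  d <- block_dims(block)
  if (d$I != object$n_models || d$K != object$n_classes) {
    abort("Block dimensions do not match the fitted combiner.")
  }
  logits <- combiner_logits(object, block$scores)
  setNames(row_argmax(logits), block$sequence_ids)
}

#' Predict with any ensemble strategy
#'
#' @param block An [score_block()].
#' @param strategy A strategy name, or a fitted `etpfam_combiner`.
#' @return Named integer vector of predicted classes.
#' @export
ensemble_predict <- function(block, strategy) {
  if (inherits(strategy, "etpfam_combiner")) return(predict(strategy, block))
  switch(strategy,
         simple = simple_vote(block),
         score = score_vote(block),
         abort(sprintf(
           "Strategy '%s' needs a fitted combiner; pass the fit_combiner() result.",
           strategy)))
}

#' @export
tidy.etpfam_combiner <- function(x, ...) {
  p <- x$params
  switch(
    x$strategy,
    lwm = tibble(model_id = x$model_ids, weight = p$w),
    lwf_perceptron = tidyr::expand_grid(
      model_id = x$model_ids, class = seq_len(x$n_classes)) |>
      dplyr::arrange(.data$class, match(.data$model_id, x$model_ids)) |>
      dplyr::mutate(weight = as.vector(p$W),
                    bias = rep(p$b, each = x$n_models)),
    tibble(term = names(p),
           n_parameters = vapply(p, length, integer(1)))
  )
}

#' @export
glance.etpfam_combiner <- function(x, ...) {
  tibble(strategy = x$strategy, n_models = x$n_models,
         n_classes = x$n_classes, trained = x$trained,
         iterations = if (is.null(x$history)) NA_integer_ else nrow(x$history),
         best_iter = x$best_iter %||% NA_integer_,
         val_loss = if (is.null(x$history)) NA_real_ else
           x$history$val_loss[x$best_iter])
}

#' Select ensemble members and trace strategy error curves
#'
#' Eligibility follows the central-window rule: only models whose CwS
#' development error is below `error_threshold` can enter the ensemble.
#' Members are then drawn in random (seeded) order from the eligible pool up
#' to `max_members`, and each strategy's development error is recorded at
#' every ensemble size so the flattening of the curve can guide the choice
#' of size.
#'
#' @param dev_scores Aggregated dev score tibble ([aggregate_tracks()]) of
#'   the method used for the curves (e.g. SwC).
#' @param dev_labels Labels as in [fit_combiner()] (tibble or vector over the
#'   dev sequences).
#' @param cws_scores Aggregated CwS dev tibble used for eligibility; defaults
#'   to `dev_scores` (i.e. when that is already CwS).
#' @param max_members Maximum ensemble size (default 10).
#' @param error_threshold CwS dev error cutoff (default 0.20).
#' @param strategies Strategies to trace; learned ones are refitted on the
#'   dev block at every size.
#' @param seed Integer seed for the random member order.
#' @param fit_args Extra arguments passed to [fit_combiner()].
#'
#' @return An `etpfam_member_selection`: list with `members` (ordered ids),
#'   `eligibility` (tibble of per-model CwS dev error), and `curve`
#'   (tibble `size`, `strategy`, `dev_error`).
#' @export
select_members <- function(dev_scores, dev_labels, cws_scores = NULL,
                           max_members = 10L, error_threshold = 0.20,
                           strategies = c("simple", "score", "lwm",
                                          "lwf_perceptron"),
                           seed = 1L, fit_args = list()) {
  cws_scores <- cws_scores %||% dev_scores
  seq_ids <- sort(unique(dev_scores$sequence_id))
  y <- align_labels(dev_labels, seq_ids)
  elig <- cws_scores |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(cws_dev_error = {
      m <- match(seq_ids, .data$sequence_id)
      mean(.data$kappa[m] != y)
    }, .groups = "drop") |>
    dplyr::mutate(eligible = .data$cws_dev_error < error_threshold)
  pool <- elig$model_id[elig$eligible]
  if (!length(pool)) {
    abort(sprintf("No model has CwS dev error below %.2f.", error_threshold))
  }
  m <- min(max_members, length(pool))
  members <- with_seed(derive_seed(seed, "members"),
                       sample(pool, m))
  curve <- list()
  for (size in seq_len(m)) {
    sub <- dplyr::filter(dev_scores, .data$model_id %in% members[seq_len(size)])
    block <- score_block(sub, model_ids = members[seq_len(size)],
                         sequence_ids = seq_ids)
    for (st in strategies) {
      pred <- if (st %in% c("simple", "score")) {
        ensemble_predict(block, st)
      } else {
        cmb <- do.call(fit_combiner,
                       c(list(strategy = st, dev_block = block,
                              dev_labels = y, seed = seed), fit_args))
        predict(cmb, block)
      }
      curve[[length(curve) + 1L]] <- tibble(
        size = size, strategy = st, dev_error = mean(pred != y))
    }
  }
  structure(list(members = members, eligibility = elig,
                 curve = dplyr::bind_rows(curve)),
            class = "etpfam_member_selection")
}

#' @export
autoplot.etpfam_member_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$size, y = .data$dev_error,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ensemble size", y = "development error",
                  colour = "strategy")
}
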