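small_config <- function(...) {
  base_model_config(W = 6, E = 4, K = 3, F = 8, Fb = 4, lr = 1e-2,
                    seed = 11, max_epochs = 5, batch_size = 16,
                    ...)
}

test_that("model construction is seeded and score vectors are softmax", {
  cfg <- small_config()
  m1 <- build_base_model(cfg)
  m2 <- build_base_model(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_base_model(base_model_config(W = 6, E = 4, K = 3, F = 8,
                                           Fb = 4, seed = 12))
  expect_false(identical(m1$params, m3$params))

  set.seed(1)
  win <- list(sequence_id = "x", nb = 0L, ne = 6L, nc = 3L,
              slice = matrix(rnorm(24), 4, 6), mask = rep(TRUE, 6),
              label = NA_integer_)
  s <- score_window(m1, win)
  expect_length(s, 3L)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(sum(s), 1, tolerance = 1e-6)
  expect_error(score_window(m1, modifyList(win, list(slice = matrix(0, 4, 5)))),
               "expects")

  # zeroed final layer gives the uniform distribution
  m1$params$W_out[] <- 0
  m1$params$b_out[] <- 0
  expect_equal(score_window(m1, win), rep(1 / 3, 3))

  # full-scale defaults echo the reference filter counts
  big <- base_model_config(W = 32, E = 1280, K = 100)
  expect_equal(big$F, 1100L)
  expect_equal(big$Fb, 550L)
})

test_that("analytic gradients match numeric differentiation", {
  ns <- asNamespace("etpfam")
  set.seed(42)
  E <- 5; W <- 7; F <- 6; Fb <- 3; K <- 4; B <- 3
  params <- ns$nn_init_params(E, W, F, Fb, K, seed = 7)
  X <- matrix(rnorm(E * W * B), E, W * B)
  mask <- matrix(TRUE, W, B); mask[6:7, 2] <- FALSE
  y <- c(1L, 3L, 2L)
  fwd <- ns$nn_forward(params, X, W, B, mask)
  ce <- ns$nn_softmax_ce(fwd$logits, y)
  grads <- ns$nn_backward(params, fwd$cache, ce$dlogits)
  loss_at <- function(p) {
    ns$nn_softmax_ce(ns$nn_forward(p, X, W, B, mask, FALSE)$logits, y)$loss
  }
  for (nm in names(params)) {
    for (t in 1:5) {
      idx <- sample(length(params[[nm]]), 1)
      eps <- 1e-6
      p2 <- params
      p2[[nm]][idx] <- p2[[nm]][idx] + eps; l1 <- loss_at(p2)
      p2[[nm]][idx] <- p2[[nm]][idx] - 2 * eps; l2 <- loss_at(p2)
      g_num <- (l1 - l2) / (2 * eps)
      g_ana <- grads[[nm]][idx]
      expect_lt(abs(g_ana - g_num) / max(1e-8, abs(g_ana) + abs(g_num)),
                1e-5)
    }
  }
})

test_that("masked pooling matches a brute-force truncated-pool oracle", {
  ns <- asNamespace("etpfam")
  cfg <- small_config()
  m <- build_base_model(cfg)
  set.seed(3)
  content <- matrix(rnorm(4 * 3), 4, 3)       # width 3 < W = 6
  p <- pad_window(content, 6)
  batch <- ns$nn_batch(list(list(sequence_id = "x", nb = 0L, ne = 3L,
                                 nc = 3L, slice = p$slice, mask = p$mask,
                                 label = NA_integer_)))
  out <- ns$nn_forward(m$params, batch$X, 6L, 1L, batch$mask)
  # oracle: identical forward pass, but pool by dropping padded columns
  H1 <- ns$relu(out$cache$Z)
  real <- which(p$mask)
  pooled <- apply(H1[, real, drop = FALSE], 1L, max)
  oracle_logits <- drop(m$params$W_out %*% pooled + m$params$b_out)
  expect_equal(drop(out$logits), oracle_logits, tolerance = 1e-12)
  # and with garbage planted in the padded columns, masked pooling still
  # never lets a padded column win
  expect_true(all(out$cache$amax <= 3L))
})

test_that("a linearly decidable toy task is learned to low dev error", {
  E <- 4; W <- 8
  train <- toy_two_class_set(100, L = W, E = E, prefix = "tr")
  dev <- toy_two_class_set(40, L = W, E = E, prefix = "dv")
  cfg <- base_model_config(W = W, E = E, K = 2, F = 8, Fb = 4, lr = 1e-2,
                           seed = 4, max_epochs = 20, batch_size = 50,
                           n_per_seq = 5)
  fit <- train_base_model(build_base_model(cfg), train, dev)
  expect_true(fit$trained)
  best <- fit$history[fit$history$epoch == fit$best_epoch, ]
  expect_lt(best$dev_error, 0.05)
  expect_lte(nrow(fit$history), 20L)
  # early stopping kept the dev-best epoch
  expect_equal(fit$best_epoch, which.min(fit$history$dev_loss))

  # reproducibility: same seed, same data -> identical history
  fit2 <- train_base_model(build_base_model(cfg), train, dev)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
})

test_that("early stopper stops after `patience` non-improvements and keeps the best", {
  es <- early_stopper(patience = 3)
  for (m in c(0.5, 0.4, 0.45, 0.42)) es <- early_stopper_update(es, m)
  expect_false(es$stop)
  expect_equal(es$best_epoch, 2L)
  es <- early_stopper_update(es, 0.41)
  expect_true(es$stop)
  expect_equal(es$best_epoch, 2L)
  expect_equal(es$best, 0.4)
  # strictly improving metric never stops
  es2 <- early_stopper(2)
  for (m in seq(1, 0.1, by = -0.1)) es2 <- early_stopper_update(es2, m)
  expect_false(es2$stop)
  expect_equal(es2$best_epoch, es2$epoch)
})

test_that("sequence scoring matches the slide enumeration and is deterministic", {
  cfg <- small_config()
  m <- build_base_model(cfg)
  set.seed(9)
  e <- embedded_sequence("q", matrix(rnorm(4 * 20), 4, 20))
  spec <- window_spec(W = 6, step = 4)
  tr <- score_sequence(m, e, spec)
  wins <- slide_windows(e, spec)
  expect_length(tr$positions, length(wins))
  expect_equal(tr$positions, vapply(wins, `[[`, integer(1), "nc"))
  for (j in seq_along(wins)) {
    expect_equal(tr$scores[j, ], score_window(m, wins[[j]]),
                 tolerance = 1e-12)
  }
  expect_equal(score_sequence(m, e, spec)$scores, tr$scores)

  # L == W: a single position, equal to scoring the whole sequence
  e6 <- embedded_sequence("q6", matrix(rnorm(4 * 6), 4, 6))
  tr6 <- score_sequence(m, e6, window_spec(W = 6, step = 4))
  expect_length(tr6$positions, 1L)
})
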