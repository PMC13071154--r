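# block from explicit per-model score rows: scores[[model]][sequence, class]
manual_block <- function(...) {
  mats <- list(...)
  n <- nrow(mats[[1]]); K <- ncol(mats[[1]]); I <- length(mats)
  arr <- array(0, dim = c(n, I, K))
  for (i in seq_len(I)) arr[, i, ] <- mats[[i]]
  structure(list(scores = arr, sequence_ids = sprintf("s%02d", seq_len(n)),
                 model_ids = sprintf("m%02d", seq_len(I)),
                 method = "manual"),
            class = "etpfam_score_block")
}

test_that("simple and score voting follow the worked examples", {
  # per-model predictions [A, A, B] -> A  (classes A=1, B=2)
  b <- manual_block(matrix(c(0.9, 0.1), 1), matrix(c(0.6, 0.4), 1),
                    matrix(c(0.2, 0.8), 1))
  expect_equal(unname(simple_vote(b)), 1L)
  # a 1-vs-1 tie resolves to the lower class index
  b2 <- manual_block(matrix(c(0.9, 0.1), 1), matrix(c(0.2, 0.8), 1))
  expect_equal(unname(simple_vote(b2)), 1L)
  # single model: its own argmax
  b1 <- manual_block(matrix(c(0.2, 0.8), 1))
  expect_equal(unname(simple_vote(b1)), 2L)
  expect_equal(unname(score_vote(b1)), 2L)

  # score voting sums scores: (0.6,0.4)+(0.1,0.9) -> class 2
  b3 <- manual_block(matrix(c(0.6, 0.4), 1), matrix(c(0.1, 0.9), 1))
  expect_equal(unname(score_vote(b3)), 2L)
})

test_that("LWM weighting follows the stated arithmetic", {
  b <- manual_block(matrix(c(0.6, 0.4), 1), matrix(c(0.1, 0.9), 1))
  # w = (2,1): class scores (1.3, 1.7) -> class 2
  expect_equal(unname(lwm_predict(b, c(2, 1))), 2L)
  # one-hot weight selects that model's argmax
  expect_equal(unname(lwm_predict(b, c(1, 0))), 1L)
  expect_error(lwm_predict(b, c(1, 1, 1)), "weights")
})

test_that("reduction chain holds on random blocks", {
  set.seed(31)
  for (trial in 1:60) {
    n <- sample(2:12, 1); I <- sample(1:5, 1); K <- sample(2:8, 1)
    b <- random_block(n, I, K)
    sv <- score_vote(b)
    expect_identical(lwm_predict(b, rep(1, I)), sv)
    lwf1 <- make_combiner("lwf_perceptron",
                          list(W = matrix(1, I, K), b = rep(0, K)), I, K)
    expect_identical(predict(lwf1, b), sv)
    Wt <- array(0, dim = c(I, K, K))
    for (k in seq_len(K)) Wt[, k, k] <- 1
    st <- make_combiner("stack_perceptron", list(W = Wt, b = rep(0, K)),
                        I, K)
    expect_identical(predict(st, b), sv)

    # one-hot scores collapse score voting onto simple voting
    hot <- b
    for (i in seq_len(I)) {
      kap <- apply(matrix(hot$scores[, i, ], n, K), 1, which.max)
      oh <- matrix(0, n, K); oh[cbind(seq_len(n), kap)] <- 1
      hot$scores[, i, ] <- oh
    }
    expect_identical(score_vote(hot), simple_vote(hot))
  }
})

test_that("voting is invariant to model order", {
  set.seed(8)
  for (trial in 1:20) {
    b <- random_block(10, 4, 5)
    perm <- sample(4)
    bp <- b
    bp$scores <- b$scores[, perm, , drop = FALSE]
    bp$model_ids <- b$model_ids[perm]
    expect_identical(unname(simple_vote(b)), unname(simple_vote(bp)))
    expect_identical(unname(score_vote(b)), unname(score_vote(bp)))
  }
})

test_that("per-class expert weights reproduce the chosen expert's score", {
  set.seed(15)
  b <- random_block(20, 2, 2)
  # class 1 listens to model 1 only, class 2 to model 2 only
  W <- matrix(c(1, 0, 0, 1), 2, 2)
  cmb <- make_combiner("lwf_perceptron", list(W = W, b = c(0, 0)), 2, 2)
  pred <- predict(cmb, b)
  expert <- apply(cbind(b$scores[, 1, 1], b$scores[, 2, 2]), 1, which.max)
  expect_equal(unname(pred), expert)

  # a dominating bias forces its class
  cb <- make_combiner("lwf_perceptron",
                      list(W = matrix(0, 2, 2), b = c(0, 100)), 2, 2)
  expect_true(all(predict(cb, b) == 2L))
})

test_that("stacking agrees with an independent dense-algebra oracle", {
  set.seed(23)
  n <- 8; I <- 3; K <- 4
  b <- random_block(n, I, K)
  Wt <- array(rnorm(I * K * K), dim = c(I, K, K))
  bias <- rnorm(K)
  cmb <- make_combiner("stack_perceptron", list(W = Wt, b = bias), I, K)
  pred <- predict(cmb, b)
  # brute force: logit[n, k] = sum_l sum_i w[i, l, k] * s[n, i, l] + b[k]
  for (nn in seq_len(n)) {
    logit <- numeric(K)
    for (k in seq_len(K)) {
      acc <- bias[k]
      for (l in seq_len(K)) for (i in seq_len(I)) {
        acc <- acc + Wt[i, l, k] * b$scores[nn, i, l]
      }
      logit[k] <- acc
    }
    expect_equal(unname(pred[nn]), which.max(logit))
  }
})

test_that("fitting is refused where there is nothing to fit, and prediction where unfitted", {
  b <- random_block(10, 2, 3)
  y <- sample.int(3, 10, replace = TRUE)
  expect_error(fit_combiner("simple", b, y), "nothing to fit")
  expect_error(fit_combiner("votes", b, y), "Unknown")
  unfit <- structure(list(strategy = "lwm", params = list(w = c(1, 1)),
                          n_models = 2L, n_classes = 3L, trained = FALSE),
                     class = "etpfam_combiner")
  expect_error(predict(unfit, b), "unfitted")
})

test_that("LWM learns to trust the reliable model", {
  # model 1 always right, model 2 always wrong
  sp <- score_block_spec(2, 4, rbind(rep(1, 4), rep(0, 4)), seed = 2)
  y <- rep(1:4, length.out = 400)
  dev <- generate_score_block(sp, y)
  cmb <- fit_combiner("lwm", dev$block, dev$labels, seed = 1)
  w <- cmb$params$w
  expect_gt(w[1], w[2])
  err <- mean(predict(cmb, dev$block) != y)
  expect_lte(err, 1)        # sanity
  expect_lt(err, 0.05)      # follows model 1, far below model 2's error (1.0)
})

test_that("LWF resolves complementary per-family experts that defeat LWM", {
  # model 1 expert on classes 1-2, model 2 expert on classes 3-4
  rel <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  y <- rep(1:4, length.out = 600)
  dev <- generate_score_block(score_block_spec(2, 4, rel, seed = 3), y)
  test <- generate_score_block(score_block_spec(2, 4, rel, seed = 4), y)
  single_errs <- vapply(1:2, function(i) {
    kap <- apply(test$block$scores[, i, ], 1, which.max)
    mean(kap != y)
  }, numeric(1))
  expect_true(all(single_errs >= 0.4))  # each expert fails half the classes
  lwf <- fit_combiner("lwf_perceptron", dev$block, dev$labels, seed = 5)
  err_lwf <- mean(predict(lwf, test$block) != y)
  expect_lt(err_lwf, 0.05)
  expect_lt(err_lwf, min(single_errs))

  # determinism: same seed and inputs give identical parameters
  lwf2 <- fit_combiner("lwf_perceptron", dev$block, dev$labels, seed = 5)
  expect_identical(lwf$params, lwf2$params)
  # and the fit history never worsens at its early-stopping optimum
  expect_equal(lwf$best_iter, which.min(lwf$history$val_loss))
})

test_that("MLP heads fit the same specialization scenario", {
  rel <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  y <- rep(1:4, length.out = 400)
  dev <- generate_score_block(score_block_spec(2, 4, rel, seed = 6), y)
  for (st in c("lwf_mlp", "stack_mlp")) {
    cmb <- fit_combiner(st, dev$block, dev$labels, seed = 7, hidden = 16)
    expect_lt(mean(predict(cmb, dev$block) != y), 0.1)
  }
})

test_that("member selection filters on CwS dev error and traces curves", {
  set.seed(40)
  n <- 20
  y <- rep(1:2, each = 10)
  # hand-built CwS tables: model errors 0.10, 0.25, 0.15
  mk <- function(model_id, n_wrong) {
    kap <- y
    kap[seq_len(n_wrong)] <- 3L - kap[seq_len(n_wrong)]
    tibble::tibble(
      sequence_id = sprintf("s%04d", seq_len(n)), model_id = model_id,
      method = "cws", kappa = kap,
      s = lapply(kap, function(k) { v <- c(0.1, 0.1); v[k] <- 0.9; v / sum(v) }))
  }
  scores <- dplyr::bind_rows(mk("m1", 2), mk("m2", 5), mk("m3", 3))
  labels <- tibble::tibble(sequence_id = sprintf("s%04d", seq_len(n)),
                           class = y)
  sel <- select_members(scores, labels, max_members = 10,
                        strategies = c("simple", "score"), seed = 2)
  expect_equal(sel$eligibility$cws_dev_error[order(sel$eligibility$model_id)],
               c(0.10, 0.25, 0.15))
  expect_setequal(sel$members, c("m1", "m3"))
  expect_equal(sort(unique(sel$curve$size)), 1:2)
  # size-1 curve equals the chosen first member's own error
  first_err <- sel$eligibility$cws_dev_error[
    sel$eligibility$model_id == sel$members[1]]
  expect_equal(unique(sel$curve$dev_error[sel$curve$size == 1]), first_err)
  expect_error(select_members(scores, labels, error_threshold = 0.05),
               "below")
})

test_that("tidy and glance expose combiner structure", {
  b <- random_block(30, 2, 3)
  y <- sample.int(3, 30, replace = TRUE)
  cmb <- fit_combiner("lwf_perceptron", b, y, seed = 1)
  td <- tidy(cmb)
  expect_equal(nrow(td), 6L)  # I * K
  expect_true(all(c("model_id", "class", "weight", "bias") %in% names(td)))
  gl <- glance(cmb)
  expect_equal(gl$strategy, "lwf_perceptron")
  expect_true(gl$trained)
})
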