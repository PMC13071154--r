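labels_of <- function(classes, ids = sprintf("q%03d", seq_along(classes))) {
  tibble::tibble(sequence_id = ids, family = sprintf("class_%d", classes),
                 class = classes, is_primary = TRUE)
}

# independent confusion-matrix oracle
brute_confusion <- function(pred, truth, K) {
  cm <- matrix(0L, K, K)
  for (j in seq_along(pred)) cm[truth[j], pred[j]] <- cm[truth[j], pred[j]] + 1L
  cm
}

test_that("error rate equals the misclassified fraction", {
  lab <- labels_of(c(1L, 1L, 2L, 2L))
  pred <- tibble::tibble(sequence_id = lab$sequence_id,
                         class = c(1L, 1L, 2L, 1L))
  expect_equal(error_rate(pred, lab), 0.25)
  expect_equal(error_rate(dplyr::mutate(pred, class = lab$class), lab), 0)
  expect_error(error_rate(pred[1:3, ], lab), "do not match")
})

test_that("error rate matches the confusion-matrix oracle on random instances", {
  set.seed(55)
  for (trial in 1:100) {
    n <- sample(5:60, 1); K <- sample(2:9, 1)
    truth <- sample.int(K, n, replace = TRUE)
    pred <- sample.int(K, n, replace = TRUE)
    lab <- labels_of(truth)
    e <- error_rate(tibble::tibble(sequence_id = lab$sequence_id,
                                   class = pred), lab)
    cm <- brute_confusion(pred, truth, K)
    expect_equal(e, 1 - sum(diag(cm)) / n, tolerance = 1e-12)
  }
})

test_that("per-family F1 follows the formula and the macro-mean convention", {
  # one family with TP=2, FP=1, FN=1 -> F1 = 4/6
  truth <- c(1L, 1L, 1L, 2L, 2L)
  pred <- c(1L, 1L, 2L, 1L, 2L)
  lab <- labels_of(truth)
  m <- f1_table(tibble::tibble(sequence_id = lab$sequence_id, class = pred),
                lab)
  fam1 <- m$per_family[1, ]
  expect_equal(c(fam1$TP, fam1$FP, fam1$FN), c(2L, 1L, 1L))
  expect_equal(fam1$f1, 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(fam1$error, 1 - fam1$recall)

  # perfect predictions: every family F1 = 1, micro error 0
  mp <- f1_table(tibble::tibble(sequence_id = lab$sequence_id,
                                class = truth), lab)
  expect_true(all(mp$per_family$f1[mp$per_family$n_test > 0] == 1))
  expect_equal(mp$micro_error, 0)

  # a family never predicted and absent from test is excluded from the macro mean
  lab3 <- labels_of(c(1L, 2L))
  m3 <- f1_table(tibble::tibble(sequence_id = lab3$sequence_id,
                                class = c(1L, 2L)),
                 lab3,
                 family_index = tibble::tibble(
                   family = c("class_1", "class_2", "ghost"), class = 1:3))
  expect_equal(m3$per_family$n_test, c(1L, 1L, 0L))
  expect_equal(m3$macro_f1, 1)
})

test_that("f1 table agrees with the confusion-matrix oracle and conserves counts", {
  set.seed(77)
  for (trial in 1:100) {
    n <- sample(5:60, 1); K <- sample(2:8, 1)
    truth <- sample.int(K, n, replace = TRUE)
    pred <- sample.int(K, n, replace = TRUE)
    lab <- labels_of(truth)
    m <- f1_table(tibble::tibble(sequence_id = lab$sequence_id,
                                 class = pred), lab)
    cm <- brute_confusion(pred, truth, K)
    pf <- m$per_family
    for (k in seq_len(K)) {
      expect_equal(pf$TP[k], cm[k, k])
      expect_equal(pf$FP[k], sum(cm[, k]) - cm[k, k])
      expect_equal(pf$FN[k], sum(cm[k, ]) - cm[k, k])
    }
    # conservation: sum(TP) + sum(FN) = number of test sequences
    expect_equal(sum(pf$TP) + sum(pf$FN), n)
    # micro error is invariant to a family relabeling permutation
    perm <- sample(K)
    m2 <- f1_table(tibble::tibble(sequence_id = lab$sequence_id,
                                  class = perm[pred]),
                   labels_of(perm[truth], ids = lab$sequence_id))
    expect_equal(m2$micro_error, m$micro_error)
  }
})

test_that("multi-domain sequences count as correct on any annotated family", {
  lab <- tibble::tibble(
    sequence_id = c("md", "md", "sd"),
    family = c("class_1", "class_2", "class_3"),
    class = c(1L, 2L, 3L),
    is_primary = c(TRUE, FALSE, TRUE))
  pred <- tibble::tibble(sequence_id = c("md", "sd"), class = c(2L, 3L))
  expect_equal(error_rate(pred, lab), 0)
  # a miss is attributed to the primary family
  pred2 <- tibble::tibble(sequence_id = c("md", "sd"), class = c(3L, 3L))
  m <- f1_table(pred2, lab)
  expect_equal(m$per_family$FN[1], 1L)
})

test_that("rescue analysis lists families going from full error to none", {
  lab <- labels_of(c(1L, 1L, 2L, 3L))
  worst <- tibble::tibble(sequence_id = lab$sequence_id,
                          class = c(2L, 2L, 2L, 3L))  # family 1 all wrong
  best <- tibble::tibble(sequence_id = lab$sequence_id,
                         class = c(1L, 1L, 2L, 3L))
  ma <- f1_table(worst, lab)
  mb <- f1_table(best, lab)
  r <- rescue_analysis(ma, mb)
  expect_equal(r$families, "class_1")
  expect_equal(r$n_full_error_a, 1L)
  expect_equal(r$n_rescued, 1L)
  expect_length(rescue_analysis(ma, ma)$families, 0L)
  expect_length(rescue_analysis(mb, mb)$families, 0L)
})

test_that("k-mer similarity hits its boundary cases", {
  expect_equal(kmer_similarity("MKVLAMKVLA", "MKVLAMKVLA"), 1)
  expect_equal(kmer_similarity("AAAAAA", "CCCCCC"), 0)
  expect_equal(kmer_similarity("MK", "MK"), 0)  # shorter than k
})

test_that("family similarity takes the mean of per-protein maxima", {
  train <- seq_tbl(c("t1", "t2"), c("MKVLAMKVLA", "CCCCCCCCCC"))
  test <- seq_tbl(c("x1", "x2"), c("MKVLAMKVLA", "WWWWWWWWWW"))
  train_lab <- tibble::tibble(sequence_id = c("t1", "t2"),
                              family = c("A", "A"))
  test_lab <- tibble::tibble(sequence_id = c("x1", "x2"),
                             family = c("A", "A"))
  fs <- family_similarity(train, test, train_lab, test_lab)
  expect_equal(fs$similarity, (1 + 0) / 2)
})

test_that("binned performance rises for a size-dependent construction", {
  # two families: tiny one always missed, big one always hit
  truth <- c(1L, rep(2L, 9))
  pred <- c(2L, rep(2L, 9))
  lab <- labels_of(truth)
  m <- f1_table(tibble::tibble(sequence_id = lab$sequence_id, class = pred),
                lab, n_train = c(class_1 = 1L, class_2 = 1000L))
  curve <- binned_performance(m, "train_family_size", n_bins = 2)
  expect_equal(nrow(curve), 2L)
  expect_lt(curve$mean_f1[1], curve$mean_f1[2])

  sim <- tibble::tibble(family = c("class_1", "class_2"),
                        similarity = c(0, 1))
  curve2 <- binned_performance(m, "test_to_train_similarity",
                               similarity = sim, n_bins = 2)
  expect_lt(curve2$mean_f1[1], curve2$mean_f1[2])
})
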