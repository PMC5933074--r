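# Self-training streams, adaptive threshold, vote confidence, RSE ensembles

test_that("prediction_distance matches the margin arithmetic", {
  expect_equal(prediction_distance(make_scores(c(0.4, 0.05, 0))), 0.375)
  expect_equal(prediction_distance(make_scores(rep(0.2, 4))), 0)
  expect_equal(prediction_distance(make_scores(c(0.7, 0.3))), 0.4)
  expect_error(prediction_distance(make_scores(0.5), K = 1), "two classes")
})

test_that("adaptive_threshold averages the distance history", {
  st <- list(alpha = 1, distance_history = c(0.2, 0.4))
  expect_equal(adaptive_threshold(st, 3), 0.3)
  st$alpha <- 0.7
  expect_equal(adaptive_threshold(st, 3), 0.21)
  st$alpha <- 0
  expect_equal(adaptive_threshold(st, 3), 0)
  expect_error(adaptive_threshold(st, 1), "never thresholded")
  expect_error(adaptive_threshold(list(alpha = 1, distance_history = 0.1), 3),
               "fewer than")
})

test_that("self-training stream honors the update contract", {
  toy <- make_toy_problem(n_test = 40, noise = 2, sep = 1.5, seed = 13)
  m0 <- ncol(toy$train$A)

  # a single test sample never updates the dictionary
  r1 <- classify_stream_semisrc_ave(toy$train, toy$test[, 1, drop = FALSE])
  expect_identical(ncol(r1$state$dictionary$A), m0)
  expect_false(r1$state$update_log$accepted[1])

  # empty stream: no predictions, dictionary untouched
  r0 <- classify_stream_semisrc_ave(toy$train,
                                    toy$test[, integer(0), drop = FALSE])
  expect_length(r0$predictions, 0)
  expect_identical(ncol(r0$state$dictionary$A), m0)

  r <- classify_stream_semisrc_ave(toy$train, toy$test, alpha = 1)
  lg <- r$state$update_log
  # distances recorded for every sample, accepted or not, and nonnegative
  expect_length(r$state$distance_history, 40)
  expect_true(all(r$state$distance_history >= 0))
  # growth bookkeeping: accepted count == dictionary growth <= m - 1
  expect_identical(ncol(r$state$dictionary$A) - m0, sum(lg$accepted))
  expect_lte(sum(lg$accepted), 39)
  # logged thresholds reproduce adaptive_threshold on the same history
  for (m in c(2, 17, 40))
    expect_equal(lg$threshold[m],
                 adaptive_threshold(r$state, m))
  # accepted samples carry their predicted label in the grown dictionary
  grown_labels <- r$state$dictionary$labels[-(1:m0)]
  expect_identical(grown_labels, r$predictions[lg$accepted])
})

test_that("huge alpha reproduces plain SRC-AVE prediction-for-prediction", {
  toy <- make_toy_problem(n_test = 25, noise = 2, sep = 1.5, seed = 17)
  frozen <- classify_stream_semisrc_ave(toy$train, toy$test, alpha = 1e9)
  expect_identical(sum(frozen$state$update_log$accepted), 0L)
  static <- vapply(seq_len(ncol(toy$test)), function(m)
    predict_src_ave(score_src(toy$train, toy$test[, m])), integer(1))
  expect_identical(frozen$predictions, static)
})

test_that("naive updating grows the dictionary by exactly n columns", {
  toy <- make_toy_problem(n_test = 18, seed = 19)
  m0 <- ncol(toy$train$A)
  r <- classify_stream_naive(toy$train, toy$test)
  expect_identical(ncol(r$state$dictionary$A), m0 + 18L)
  expect_true(all(r$state$update_log$accepted))
  # on cleanly separable data the naive and gated variants agree
  gated <- classify_stream_semisrc_ave(toy$train, toy$test)
  expect_identical(r$predictions, gated$predictions)
  expect_identical(r$predictions, toy$test_labels)
})

test_that("accepted updates are non-increasing in alpha on a fixed stream", {
  toy <- make_toy_problem(n_test = 50, noise = 2.5, sep = 1.2, seed = 23)
  ups <- vapply(c(0, 0.5, 0.8, 1, 1.3, 2, 5), function(a)
    sum(classify_stream_semisrc_ave(toy$train, toy$test,
                                    alpha = a)$state$update_log$accepted),
    integer(1))
  expect_true(all(diff(ups) <= 0))
  expect_gt(ups[1], 0)     # alpha = 0 accepts every positive-margin sample
})

test_that("with updates disabled predictions are permutation-invariant", {
  toy <- make_toy_problem(n_test = 30, noise = 2, seed = 29)
  perm <- withr::with_seed(1, sample(30))
  base <- classify_stream_semisrc_ave(toy$train, toy$test, alpha = 1e9)
  permuted <- classify_stream_semisrc_ave(toy$train, toy$test[, perm],
                                          alpha = 1e9)
  expect_identical(permuted$predictions, base$predictions[perm])
})

test_that("vote_confidence takes the majority with ties to the lowest id", {
  expect_identical(vote_confidence(c(1, 1, 2, 1)),
                   list(label = 1, confidence = 0.75))
  expect_identical(vote_confidence(rep(3L, 5)),
                   list(label = 3L, confidence = 1))
  expect_identical(vote_confidence(c(2, 1)),
                   list(label = 1, confidence = 0.5))
  expect_error(vote_confidence(integer(0)), "empty")
})

test_that("ensemble configuration draws valid reproducible subsets", {
  cfg <- ensemble_config(50, n_classifiers = 8, subspace_size = 10, seed = 99)
  expect_length(cfg$feature_subsets, 8)
  for (fs in cfg$feature_subsets) {
    expect_length(fs, 10)
    expect_false(anyDuplicated(fs) > 0)
    expect_true(all(fs >= 1 & fs <= 50))
  }
  cfg2 <- ensemble_config(50, n_classifiers = 8, subspace_size = 10,
                          seed = 99)
  expect_identical(cfg$feature_subsets, cfg2$feature_subsets)
  expect_error(ensemble_config(50, subspace_size = 50), "smaller")
})

test_that("random-subspace streams vote, gate and update", {
  toy <- make_toy_problem(n_test = 30, p = 40, noise = 1.5, seed = 37)
  cfg <- ensemble_config(40, n_classifiers = 5, subspace_size = 12, seed = 3)

  for (base in c("src_ave", "ldc")) {
    r <- classify_stream_rse(toy$train, toy$test, cfg, base = base)
    expect_length(r$predictions, 30)
    expect_true(all(r$update_log$confidence >= 1 / 3 - 1e-12 &
                      r$update_log$confidence <= 1))
    # determinism: identical config, identical predictions
    r2 <- classify_stream_rse(toy$train, toy$test, cfg, base = base)
    expect_identical(r$predictions, r2$predictions)
    # confidence threshold above 1 freezes the ensemble (static limit)
    frozen <- ensemble_config(40, n_classifiers = 5, subspace_size = 12,
                              seed = 3, confidence_threshold = 1.1)
    rf <- classify_stream_rse(toy$train, toy$test, frozen, base = base)
    expect_identical(sum(rf$update_log$accepted), 0L)
  }

  # L = 1 reduces to the base classifier on one subspace, confidence 1
  cfg1 <- ensemble_config(40, n_classifiers = 1, subspace_size = 12, seed = 7)
  r1 <- classify_stream_rse(toy$train, toy$test, cfg1, base = "ldc")
  expect_true(all(r1$update_log$confidence == 1))
  expect_true(all(r1$update_log$accepted))
  expect_error(classify_stream_rse(
    toy$train, toy$test,
    ensemble_config(80, n_classifiers = 2, subspace_size = 60), "ldc"),
    "smaller")
})
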