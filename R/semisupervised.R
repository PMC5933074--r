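#' Confidence distance of an average-coefficient prediction
#'
#' For a query scored against a K-class dictionary, the distance
#' `d_m = S_I - mean(S_j, j != I)` between the predicted class's average
#' coefficient and the mean of the other classes' averages. Because the
#' predicted class has the maximal average, `d_m >= 0` always.
#'
#' @param scores a `class_scores` object from [score_src()].
#' @param K class count (>= 2); defaults to the number of classes scored.
#' @return The nonnegative distance.
#' @export
prediction_distance <- function(scores, K = length(scores$averages)) {
  stopifnot(inherits(scores, "class_scores"))
  if (K < 2) stop("prediction distance needs at least two classes")
  if (length(scores$averages) != K)
    stop("scores carry ", length(scores$averages), " averages, expected ", K)
  i <- if (!is.na(scores$predicted)) {
    match(scores$predicted, scores$classes)
  } else {
    which.max(scores$averages)
  }
  scores$averages[[i]] - sum(scores$averages[-i]) / (K - 1)
}

#' Adaptive self-training acceptance threshold
#'
#' The threshold for the m-th test sample is `alpha` times the mean of the
#' distances of all previous test samples (accepted or not). The first test
#' sample is never thresholded, so `m >= 2` is required.
#'
#' @param state a `self_train_state` (or any list with `alpha` and
#'   `distance_history`).
#' @param m index of the test sample about to be judged (>= 2).
#' @return The threshold value.
#' @export
adaptive_threshold <- function(state, m) {
  if (m < 2) stop("the first test sample is never thresholded (m must be >= 2)")
  dh <- state$distance_history
  if (length(dh) < m - 1) stop("distance history has fewer than m - 1 entries")
  state$alpha * mean(dh[seq_len(m - 1)])
}

new_self_train_state <- function(dictionary, alpha, distance_history,
                                 update_log) {
  structure(list(dictionary = dictionary, alpha = alpha,
                 distance_history = distance_history,
                 update_log = update_log),
            class = "self_train_state")
}

#' @export
print.self_train_state <- function(x, ...) {
  cat("<self_train_state> ", length(x$distance_history),
      " test samples processed, ", sum(x$update_log$accepted),
      " accepted into the dictionary (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

# Shared engine of the self-training sparse decoders. Keeps a preallocated
# dictionary and Gram cache so appending a column is O(N*M), and warm-starts
# each solve from the previous test sample's code.
selftrain_engine <- function(train, test, alpha, settings, accept_all,
                             normalize_updates, warm_start = FALSE) {
  stopifnot(inherits(train, "labeled_dictionary"))
  test <- as.matrix(test)
  p <- nrow(train$A)
  if (ncol(test) > 0L && nrow(test) != p)
    stop("test feature dimension does not match the dictionary")
  classes <- train$classes
  K <- length(classes)
  if (K < 2) stop("self-training needs at least two classes")
  n <- ncol(test)
  m0 <- ncol(train$A)
  mmax <- m0 + n
  Amat <- matrix(0, p, mmax)
  Amat[, seq_len(m0)] <- train$A
  G <- matrix(0, mmax, mmax)
  G[seq_len(m0), seq_len(m0)] <- crossprod(train$A)
  labels <- c(train$labels, rep(train$labels[1], n))
  li <- match(labels, classes)
  counts <- tabulate(li[seq_len(m0)], K)
  M <- m0
  dhist <- numeric(n)
  preds <- rep(classes[1], n)
  log_pred <- preds
  log_d <- numeric(n)
  log_thr <- rep(NA_real_, n)
  log_acc <- logical(n)
  xprev <- NULL
  for (m in seq_len(n)) {
    y <- test[, m]
    cvec <- as.numeric(crossprod(Amat, y))[seq_len(M)]
    tau <- settings$tau %||% (settings$tau_scale * max(abs(cvec)))
    if (!is.finite(tau)) tau <- 0
    x0 <- if (warm_start && !is.null(xprev)) c(xprev, numeric(M - length(xprev)))
    res <- gpsr_gram_cpp(G, cvec, sum(y^2), tau, settings$tol,
                         settings$max_iter, x0)
    x <- res$x
    xprev <- x
    csum <- numeric(K)
    sums <- rowsum(x, li[seq_len(M)])
    csum[as.integer(rownames(sums))] <- sums[, 1]
    avg <- csum / counts
    pi <- which.max(avg)
    pred <- classes[pi]
    d <- avg[pi] - sum(avg[-pi]) / (K - 1)
    thr <- if (m > 1) alpha * mean(dhist[seq_len(m - 1)]) else NA_real_
    accepted <- accept_all || (m > 1 && d > thr)
    dhist[m] <- d
    preds[m] <- pred
    log_pred[m] <- pred
    log_d[m] <- d
    log_thr[m] <- thr
    log_acc[m] <- accepted
    if (accepted) {
      col <- if (normalize_updates) zscore_vec(y) else y
      M <- M + 1L
      Amat[, M] <- col
      labels[M] <- pred
      li[M] <- pi
      counts[pi] <- counts[pi] + 1L
      g <- as.numeric(crossprod(Amat, col))[seq_len(M)]
      G[seq_len(M), M] <- g
      G[M, seq_len(M)] <- g
      xprev <- c(xprev, 0)
    }
  }
  dict <- labeled_dictionary(Amat[, seq_len(M), drop = FALSE],
                             labels[seq_len(M)])
  log <- data.frame(index = seq_len(n), predicted = log_pred, distance = log_d,
                    threshold = log_thr, accepted = log_acc)
  list(predictions = preds,
       state = new_self_train_state(dict, alpha, dhist[seq_len(n)], log))
}

#' Self-training average-coefficient sparse decoder (semiSRC-AVE)
#'
#' Processes an ordered stream of unlabeled test volumes. Each volume is
#' sparse-coded against the current dictionary and classified by the maximal
#' per-class average coefficient. Its confidence distance `d_m` is compared
#' to the adaptive threshold ([adaptive_threshold()]): if `d_m` exceeds it
#' (strictly), the volume and its predicted label are appended to the
#' dictionary before the next volume is processed. The first test volume
#' never updates the dictionary, but its distance does enter the history.
#'
#' @param train a [labeled_dictionary()] of labeled training volumes.
#' @param test matrix of test volumes (features x time, processed in column
#'   order).
#' @param alpha threshold coefficient; 1 is the usual choice when training
#'   and testing tasks coincide, 0.7 for cross-decoding. Very large `alpha`
#'   disables updating and reproduces plain SRC-AVE.
#' @param settings a [solver_settings()].
#' @param normalize_updates z-score appended columns (see [append_sample()]).
#' @return A list with `predictions` (one class id per test column) and
#'   `state` (a `self_train_state`: final dictionary, distance history and
#'   per-sample update log).
#' @export
classify_stream_semisrc_ave <- function(train, test, alpha = 1,
                                        settings = solver_settings(),
                                        normalize_updates = TRUE) {
  selftrain_engine(train, test, alpha, settings, accept_all = FALSE,
                   normalize_updates = normalize_updates)
}

#' Naive self-training sparse decoder
#'
#' Like [classify_stream_semisrc_ave()] but with no confidence gate: every
#' test volume (including the first) is appended to the dictionary with its
#' predicted label. After n test volumes the dictionary has grown by exactly
#' n columns.
#'
#' @inheritParams classify_stream_semisrc_ave
#' @return As [classify_stream_semisrc_ave()].
#' @export
classify_stream_naive <- function(train, test,
                                  settings = solver_settings(),
                                  normalize_updates = TRUE) {
  selftrain_engine(train, test, alpha = 0, settings = settings,
                   accept_all = TRUE, normalize_updates = normalize_updates)
}

#' Majority vote and its confidence
#'
#' @param votes label predictions of the ensemble members.
#' @return A list with `label` (majority label, ties to the lowest class id)
#'   and `confidence` (fraction of members agreeing with the majority).
#' @export
vote_confidence <- function(votes) {
  if (length(votes) == 0L) stop("empty vote")
  classes <- sort(unique(votes))
  counts <- tabulate(match(votes, classes), length(classes))
  i <- which.max(counts)
  list(label = classes[i], confidence = counts[i] / length(votes))
}

#' Random-subspace ensemble configuration
#'
#' Draws the L feature subsets (size M, sampled without replacement) once
#' from the stated seed; the same subsets are used for training and testing.
#'
#' @param n_features total feature count n.
#' @param n_classifiers ensemble size L.
#' @param subspace_size subset size M (< n); default `ceiling(n / 10)`.
#' @param confidence_threshold vote-confidence level strictly above which a
#'   test sample is fed back to every member.
#' @param seed RNG seed for drawing the subsets.
#' @return A list of class `ensemble_config` including `feature_subsets`.
#' @export
ensemble_config <- function(n_features, n_classifiers = 25L,
                            subspace_size = ceiling(n_features / 10),
                            confidence_threshold = 0.75, seed = 1L) {
  if (subspace_size >= n_features)
    stop("subspace size must be smaller than the feature count")
  stopifnot(n_classifiers >= 1, subspace_size >= 1,
            confidence_threshold >= 0)
  subsets <- withr::with_seed(seed, lapply(seq_len(n_classifiers), function(l)
    sort(sample.int(n_features, subspace_size))))
  structure(list(n_classifiers = as.integer(n_classifiers),
                 subspace_size = as.integer(subspace_size),
                 confidence_threshold = confidence_threshold,
                 feature_subsets = subsets, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Random-subspace online ensemble decoder (RSE-OLDC / RSE-OSRC-AVE)
#'
#' L base classifiers each operate on their own random feature subset; the
#' stream prediction is the majority vote. When the vote confidence exceeds
#' the threshold (strictly), the test volume with its predicted label is added
#' to every member's training data: discriminant members are refit exactly,
#' sparse members gain a dictionary column.
#'
#' @param train a [labeled_dictionary()].
#' @param test matrix of test volumes (features x time).
#' @param config an [ensemble_config()] drawn for `nrow(train$A)` features.
#' @param base `"ldc"` for linear discriminant members (RSE-OLDC) or
#'   `"src_ave"` for average-coefficient sparse members (RSE-OSRC-AVE).
#' @param settings a [solver_settings()] (sparse members only).
#' @param normalize_updates z-score appended volumes in the full feature
#'   space before restriction to the member subspaces.
#' @return A list with `predictions`, `update_log` (index, predicted,
#'   confidence, accepted) and `config`.
#' @export
classify_stream_rse <- function(train, test, config,
                                base = c("src_ave", "ldc"),
                                settings = solver_settings(),
                                normalize_updates = TRUE) {
  base <- match.arg(base)
  stopifnot(inherits(train, "labeled_dictionary"),
            inherits(config, "ensemble_config"))
  test <- as.matrix(test)
  p <- nrow(train$A)
  if (config$subspace_size >= p)
    stop("subspace size must be smaller than the feature count")
  if (ncol(test) > 0L && nrow(test) != p)
    stop("test feature dimension does not match the dictionary")
  classes <- train$classes
  K <- length(classes)
  L <- config$n_classifiers
  n <- ncol(test)
  m0 <- ncol(train$A)
  mmax <- m0 + n
  subsets <- do.call(cbind, config$feature_subsets)
  if (base == "ldc") {
    members <- lapply(config$feature_subsets, function(fs)
      fit_ldc(train$A[fs, , drop = FALSE], train$labels))
  } else {
    Acube <- array(0, dim = c(config$subspace_size, mmax, L))
    for (l in seq_len(L))
      Acube[, seq_len(m0), l] <- train$A[config$feature_subsets[[l]], ,
                                         drop = FALSE]
    labels <- c(train$labels, rep(train$labels[1], n))
    li <- match(labels, classes)
    counts <- tabulate(li[seq_len(m0)], K)
    Xwarm <- matrix(0, mmax, L)
  }
  M <- m0
  preds <- rep(classes[1], n)
  log_conf <- numeric(n)
  log_acc <- logical(n)
  for (m in seq_len(n)) {
    y <- test[, m]
    if (base == "ldc") {
      votes <- vapply(seq_len(L), function(l)
        predict_ldc(members[[l]], y[subsets[, l]]),
        vector(mode = typeof(classes), length = 1L))
    } else {
      vi <- rse_srcave_votes_cpp(Acube, subsets, y, M, li[seq_len(M)],
                                 counts, settings$tau_scale,
                                 settings$tau %||% -1, settings$tol,
                                 settings$max_iter, Xwarm)
      votes <- classes[vi]
    }
    v <- vote_confidence(votes)
    preds[m] <- v$label
    log_conf[m] <- v$confidence
    accepted <- v$confidence > config$confidence_threshold
    log_acc[m] <- accepted
    if (accepted) {
      col <- if (normalize_updates) zscore_vec(y) else y
      if (base == "ldc") {
        for (l in seq_len(L))
          members[[l]] <- update_ldc(members[[l]], col[subsets[, l]],
                                     v$label)
      } else {
        M <- M + 1L
        for (l in seq_len(L))
          Acube[, M, l] <- col[subsets[, l]]
        labels[M] <- v$label
        pi <- match(v$label, classes)
        li[M] <- pi
        counts[pi] <- counts[pi] + 1L
      }
    }
  }
  log <- data.frame(index = seq_len(n), predicted = preds,
                    confidence = log_conf, accepted = log_acc)
  list(predictions = preds, update_log = log, config = config)
}
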