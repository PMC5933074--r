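#' Task reference regressor
#'
#' Box-car union of all task blocks convolved with the HRF, truncated to the
#' run length. Used to rank voxels for feature selection.
#'
#' @param paradigm a [make_paradigm()].
#' @param hrf HRF kernel sampled at the paradigm's TR.
#' @return Numeric vector, one value per volume.
#' @export
build_reference <- function(paradigm, hrf = canonical_hrf(paradigm$tr_seconds)) {
  stopifnot(inherits(paradigm, "paradigm"))
  conv_hrf(as.numeric(paradigm$volume_labels > 0), hrf)
}

#' Select voxels by correlation with the task reference
#'
#' Pearson correlation of every voxel's time course with the reference,
#' computed on the training run only; the top-k voxels by (signed, by
#' default) correlation are kept, and the identical index set must be applied
#' to the test run. Ties at the k-th rank break to the lowest voxel index.
#'
#' @param data training run data, volumes x voxels (a matrix or a
#'   `simulated_run`).
#' @param reference reference vector from [build_reference()].
#' @param k number of voxels to keep (clamped to the voxel count with a
#'   warning).
#' @param use_abs rank by `|r|` instead of signed r.
#' @return A list of class `feature_selection` with `selected` (indices in
#'   rank order), `correlations` and `k`.
#' @export
select_features <- function(data, reference, k = 1000, use_abs = FALSE) {
  if (inherits(data, "simulated_run")) data <- data$data
  data <- as.matrix(data)
  stopifnot(k >= 1, nrow(data) == length(reference))
  r <- suppressWarnings(as.numeric(stats::cor(data, reference)))
  r[!is.finite(r)] <- -Inf                 # constant voxels rank last
  score <- if (use_abs) abs(r) else r
  if (k > ncol(data)) {
    warning("k = ", k, " exceeds the voxel count (", ncol(data),
            "); keeping all voxels")
    k <- ncol(data)
  }
  ord <- order(-score, seq_along(score))
  structure(list(selected = ord[seq_len(k)], correlations = r,
                 k = as.integer(k), use_abs = use_abs),
            class = "feature_selection")
}

zscore_cols <- function(X, eps = 1e-12) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  X <- sweep(X, 2, mu)
  bad <- !is.finite(s) | s < eps
  s[bad] <- 1
  X <- sweep(X, 2, s, "/")
  X[, bad] <- 0
  X
}

#' Normalize a run to model-ready form
#'
#' Restricts to the selected voxels, then z-scores each voxel's time course
#' (columns) and afterwards each volume's spatial pattern (rows) - in that
#' fixed order. Constant vectors map to zeros instead of NaN.
#'
#' @param data run data, volumes x voxels (a matrix or `simulated_run`).
#' @param features a [select_features()] result, or an index vector, or
#'   `NULL` for all voxels.
#' @return Matrix, volumes x selected voxels.
#' @export
normalize_run <- function(data, features = NULL) {
  if (inherits(data, "simulated_run")) data <- data$data
  data <- as.matrix(data)
  idx <- if (is.null(features)) seq_len(ncol(data))
         else if (inherits(features, "feature_selection")) features$selected
         else as.integer(features)
  X <- data[, idx, drop = FALSE]
  X <- zscore_cols(X)
  t(zscore_cols(t(X)))
}

#' Remove a linear drift from every voxel
#'
#' Ordinary-least-squares removal of intercept and linear trend, per voxel.
#'
#' @param data run data, volumes x voxels.
#' @return Detrended matrix of the same shape.
#' @export
detrend_linear <- function(data) {
  data <- as.matrix(data)
  tn <- nrow(data)
  X <- cbind(1, seq_len(tn))
  data - X %*% solve(crossprod(X), crossprod(X, data))
}

#' Classification accuracy
#'
#' Fraction of test samples whose predicted label equals the true label.
#'
#' @param predictions,truth equal-length label vectors.
#' @return A fraction in `[0, 1]`.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("predictions and truth differ in length")
  if (length(truth) == 0L) return(NA_real_)
  mean(predictions == truth)
}

# Paired two-sided Wilcoxon signed-rank test. Exact distribution for up to
# 25 informative pairs (unless ties in |d| force the normal approximation);
# zero differences are dropped. Returns 1 when no informative pairs remain.
paired_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) return(1)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(stats::wilcox.test(d, exact = exact,
                                      correct = TRUE)$p.value)
}

#' Default analysis configuration
#'
#' One nested list mirroring every tunable default: solver (`tau_scale`,
#' `tol`, `max_iter`), feature selection (`k`, `use_abs`), self-training
#' (`alpha_same_task`, `alpha_cross`, `normalize_updates`), ensembles (`L`,
#' `subspace_frac`, `confidence_threshold`), and classification scope
#' (`include_rest`).
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(solver = list(tau_scale = 0.1, tol = 1e-6, max_iter = 1000L),
       features = list(k = 1000L, use_abs = FALSE),
       selftrain = list(alpha_same_task = 1, alpha_cross = 0.7,
                        normalize_updates = TRUE),
       ensemble = list(L = 25L, subspace_frac = 0.1,
                       confidence_threshold = 0.75, seed = 1L),
       classify = list(include_rest = FALSE))
}

#' Read / write a configuration file
#'
#' The configuration is stored as JSON; missing fields fall back to
#' [default_config()].
#'
#' @param path file path.
#' @return `read_config()` returns the merged configuration list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (sec in names(user))
    cfg[[sec]] <- modifyList(cfg[[sec]] %||% list(), as.list(user[[sec]]))
  cfg
}

#' @rdname read_config
#' @param config configuration list to write.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

config_settings <- function(config) {
  solver_settings(tau_scale = config$solver$tau_scale,
                  tol = config$solver$tol,
                  max_iter = config$solver$max_iter)
}

#' Prepare one dataset for decoding
#'
#' Runs the standard pathway: build the reference from the training
#' paradigm, select the top-k voxels on the training run only, normalize the
#' two runs independently (each with its own statistics), and keep the task
#' volumes of the requested task subset in acquisition order.
#'
#' @param dataset a `list(train, test, ...)` entry of a
#'   [generate_group()] collection.
#' @param config a [default_config()]-style list.
#' @param tasks task ids to keep (default: all tasks).
#' @return A list with `train` (a [labeled_dictionary()]), `test` (matrix,
#'   features x volumes), `test_labels`, and `features`.
#' @export
prepare_dataset <- function(dataset, config = default_config(), tasks = NULL) {
  tr_run <- dataset$train
  te_run <- dataset$test
  ref <- build_reference(tr_run$paradigm)
  fs <- select_features(tr_run, ref, k = min(config$features$k,
                                             ncol(tr_run$data)),
                        use_abs = config$features$use_abs)
  Xtr <- normalize_run(tr_run, fs)
  Xte <- normalize_run(te_run, fs)
  keep_tr <- tr_run$volume_labels > 0
  keep_te <- te_run$volume_labels > 0
  if (isTRUE(config$classify$include_rest)) {
    keep_tr[] <- TRUE
    keep_te[] <- TRUE
  }
  if (!is.null(tasks)) {
    keep_tr <- keep_tr & tr_run$volume_labels %in% tasks
    keep_te <- keep_te & te_run$volume_labels %in% tasks
  }
  list(train = labeled_dictionary(t(Xtr[keep_tr, , drop = FALSE]),
                                  tr_run$volume_labels[keep_tr]),
       test = t(Xte[keep_te, , drop = FALSE]),
       test_labels = te_run$volume_labels[keep_te],
       features = fs)
}

classifier_roster <- function() {
  c("src", "src_ave", "semisrc_ave", "naive_semisrc_ave",
    "rse_oldc", "rse_osrc_ave")
}

# Static residual-rule and average-rule predictions share one coding pass.
static_src_predictions <- function(train, test, settings) {
  n <- ncol(test)
  src <- vector(mode = typeof(train$classes), length = n)
  src_ave <- src
  for (m in seq_len(n)) {
    sc <- score_src(train, test[, m], settings)
    src[m] <- predict_src(sc)
    src_ave[m] <- predict_src_ave(sc)
  }
  list(src = src, src_ave = src_ave)
}

#' Decode one prepared dataset with one classifier
#'
#' @param prep a [prepare_dataset()] result.
#' @param method one of `"src"`, `"src_ave"`, `"semisrc_ave"`,
#'   `"naive_semisrc_ave"`, `"rse_oldc"`, `"rse_osrc_ave"`.
#' @param config configuration list.
#' @param alpha self-training threshold coefficient (defaults to the
#'   same-task value in `config`).
#' @return A list with `predictions`, `accuracy` and (for the updating
#'   methods) the update log.
#' @export
decode_dataset <- function(prep, method = "semisrc_ave",
                           config = default_config(), alpha = NULL) {
  method <- match.arg(method, classifier_roster())
  settings <- config_settings(config)
  alpha <- alpha %||% config$selftrain$alpha_same_task
  nu <- config$selftrain$normalize_updates
  out <- switch(method,
    src = list(predictions =
                 static_src_predictions(prep$train, prep$test, settings)$src),
    src_ave = list(predictions =
                     static_src_predictions(prep$train, prep$test,
                                            settings)$src_ave),
    semisrc_ave = classify_stream_semisrc_ave(prep$train, prep$test,
                                              alpha = alpha,
                                              settings = settings,
                                              normalize_updates = nu),
    naive_semisrc_ave = classify_stream_naive(prep$train, prep$test,
                                              settings = settings,
                                              normalize_updates = nu),
    rse_oldc = ,
    rse_osrc_ave = {
      p <- nrow(prep$train$A)
      cfg <- ensemble_config(
        n_features = p,
        n_classifiers = config$ensemble$L,
        subspace_size = max(1L, min(p - 1L,
                                    ceiling(config$ensemble$subspace_frac * p))),
        confidence_threshold = config$ensemble$confidence_threshold,
        seed = config$ensemble$seed)
      classify_stream_rse(prep$train, prep$test, cfg,
                          base = if (method == "rse_oldc") "ldc" else "src_ave",
                          settings = settings, normalize_updates = nu)
    })
  out$accuracy <- accuracy(out$predictions, prep$test_labels)
  out$method <- method
  out
}

#' Compare classifiers across a dataset collection
#'
#' For every dataset: select features on the training run, normalize both
#' runs, restrict to the requested task subset, and run every classifier in
#' the roster over the testing run in time order. Accuracies are tabulated
#' per (subject, CNR, classifier); mean accuracies per (CNR, classifier) and
#' paired Wilcoxon signed-rank p-values between the self-training
#' average-coefficient decoder and each competitor (paired across subjects,
#' per CNR level) are attached when available.
#'
#' @param collection a [generate_group()] result (or a list of datasets).
#' @param roster classifier names (see [decode_dataset()]).
#' @param config configuration list.
#' @param tasks task subset (default all).
#' @param alpha self-training threshold coefficient; defaults to the
#'   config's same-task value for group 1 and cross-decoding value for
#'   group 2.
#' @param keep_logs retain per-run update logs.
#' @return A list of class `experiment_result` with `accuracy` (long
#'   data.frame), `mean_accuracy`, `pvalues` and `logs`.
#' @export
compare_classifiers <- function(collection,
                                roster = c("src_ave", "semisrc_ave",
                                           "naive_semisrc_ave", "rse_oldc",
                                           "rse_osrc_ave"),
                                config = default_config(), tasks = NULL,
                                alpha = NULL, keep_logs = FALSE) {
  datasets <- if (inherits(collection, "sim_collection"))
    collection$datasets else collection
  roster <- match.arg(roster, classifier_roster(), several.ok = TRUE)
  settings <- config_settings(config)
  if (is.null(alpha)) {
    grp <- datasets[[1]]$group %||% 1
    alpha <- if (identical(grp, 2) || identical(grp, 2L))
      config$selftrain$alpha_cross else config$selftrain$alpha_same_task
  }
  rows <- list()
  logs <- list()
  for (ds in datasets) {
    prep <- prepare_dataset(ds, config, tasks)
    statics <- intersect(roster, c("src", "src_ave"))
    res <- list()
    if (length(statics) > 0) {
      both <- static_src_predictions(prep$train, prep$test, settings)
      for (m in statics)
        res[[m]] <- list(predictions = both[[m]],
                         accuracy = accuracy(both[[m]], prep$test_labels))
    }
    for (m in setdiff(roster, statics))
      res[[m]] <- decode_dataset(prep, m, config, alpha = alpha)
    for (m in roster) {
      rows[[length(rows) + 1L]] <-
        data.frame(subject = ds$subject, cnr = ds$cnr, classifier = m,
                   n_test = length(prep$test_labels),
                   accuracy = res[[m]]$accuracy)
      if (keep_logs && !is.null(res[[m]]$state))
        logs[[paste(ds$subject, ds$cnr, m, sep = "_")]] <-
          res[[m]]$state$update_log
    }
  }
  acc <- do.call(rbind, rows)
  mean_acc <- stats::aggregate(accuracy ~ cnr + classifier, acc, mean)
  pvals <- NULL
  if ("semisrc_ave" %in% roster && length(roster) > 1) {
    prows <- list()
    for (cnr in unique(acc$cnr)) {
      ref <- acc[acc$cnr == cnr & acc$classifier == "semisrc_ave", ]
      ref <- ref[order(ref$subject), ]
      for (m in setdiff(roster, "semisrc_ave")) {
        other <- acc[acc$cnr == cnr & acc$classifier == m, ]
        other <- other[order(other$subject), ]
        if (nrow(ref) >= 2 && nrow(ref) == nrow(other))
          prows[[length(prows) + 1L]] <-
            data.frame(cnr = cnr, competitor = m,
                       p = paired_wilcoxon(ref$accuracy, other$accuracy))
      }
    }
    if (length(prows) > 0) pvals <- do.call(rbind, prows)
  }
  structure(list(accuracy = acc, mean_accuracy = mean_acc, pvalues = pvals,
                 logs = logs, roster = roster, alpha = alpha, tasks = tasks),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", length(unique(x$accuracy$subject)),
      " subjects x ", length(unique(x$accuracy$cnr)), " CNR levels; roster: ",
      paste(x$roster, collapse = ", "), "\n", sep = "")
  print(x$mean_accuracy)
  invisible(x)
}

#' Sweep the self-training threshold coefficient
#'
#' Runs the three-class self-training average-coefficient decoder on every
#' dataset for each alpha on the grid; the per-alpha score is the mean
#' accuracy across subjects per CNR level, then across CNR levels. The
#' reported best alpha is the grid argmax, ties to the smaller value.
#'
#' @param collection a [generate_group()] result (typically group 2).
#' @param alphas alpha grid.
#' @param config configuration list.
#' @param tasks task subset (default all).
#' @return A list of class `alpha_sweep` with `table` (alpha, mean_accuracy)
#'   and `best_alpha`.
#' @export
sweep_alpha <- function(collection, alphas = seq(0.5, 1, by = 0.1),
                        config = default_config(), tasks = NULL) {
  datasets <- if (inherits(collection, "sim_collection"))
    collection$datasets else collection
  alphas <- sort(alphas)
  settings <- config_settings(config)
  nu <- config$selftrain$normalize_updates
  preps <- lapply(datasets, prepare_dataset, config = config, tasks = tasks)
  res <- vapply(alphas, function(a) {
    acc <- vapply(seq_along(preps), function(i) {
      r <- classify_stream_semisrc_ave(preps[[i]]$train, preps[[i]]$test,
                                       alpha = a, settings = settings,
                                       normalize_updates = nu)
      accuracy(r$predictions, preps[[i]]$test_labels)
    }, numeric(1))
    df <- data.frame(cnr = vapply(datasets, `[[`, numeric(1), "cnr"),
                     accuracy = acc)
    mean(stats::aggregate(accuracy ~ cnr, df, mean)$accuracy)
  }, numeric(1))
  tab <- data.frame(alpha = alphas, mean_accuracy = res)
  structure(list(table = tab, best_alpha = alphas[which.max(res)]),
            class = "alpha_sweep")
}

#' @export
print.alpha_sweep <- function(x, ...) {
  print(x$table)
  cat("best alpha:", x$best_alpha, "\n")
  invisible(x)
}
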