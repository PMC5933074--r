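#' Labeled training dictionary
#'
#' The matrix of labeled training samples used as the sparse coding basis:
#' one column per training volume, one class label per column. Self-training
#' grows it by appending confidently predicted test volumes.
#'
#' @param A feature x sample matrix (finite entries).
#' @param labels per-column class labels (length `ncol(A)`); every class must
#'   have at least one column.
#' @return A list of class `labeled_dictionary` with elements `A`, `labels`
#'   and `classes` (sorted unique labels).
#' @export
labeled_dictionary <- function(A, labels) {
  A <- as.matrix(A)
  if (!all(is.finite(A))) stop("non-finite entries in dictionary")
  if (ncol(A) < 1L) stop("dictionary must have at least one column")
  if (length(labels) != ncol(A))
    stop("labels length does not match dictionary column count")
  structure(list(A = A, labels = labels, classes = sort(unique(labels))),
            class = "labeled_dictionary")
}

#' Append one labeled sample to a dictionary
#'
#' @param dict a [labeled_dictionary()].
#' @param y sample vector (length `nrow(dict$A)`).
#' @param label its class label.
#' @param normalize z-score the sample (zero mean, unit variance across
#'   features) before insertion so appended columns stay on the same scale as
#'   the normalized training columns. Idempotent on already z-scored input.
#' @return The grown dictionary.
#' @export
append_sample <- function(dict, y, label, normalize = TRUE) {
  stopifnot(inherits(dict, "labeled_dictionary"))
  y <- as.numeric(y)
  if (length(y) != nrow(dict$A)) stop("sample dimension mismatch")
  if (normalize) y <- zscore_vec(y)
  dict$A <- cbind(dict$A, y, deparse.level = 0)
  dict$labels <- c(dict$labels, label)
  if (!label %in% dict$classes) dict$classes <- sort(c(dict$classes, label))
  dict
}

#' @export
print.labeled_dictionary <- function(x, ...) {
  cat("<labeled_dictionary> ", nrow(x$A), " features x ", ncol(x$A),
      " samples; classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

zscore_vec <- function(y, eps = 1e-12) {
  s <- stats::sd(y)
  if (!is.finite(s) || s < eps) return(rep(0, length(y)))
  (y - mean(y)) / s
}

#' Per-class scores of a sparse code
#'
#' Codes a query against a labeled dictionary and summarizes the code per
#' class: the reconstruction residual `r_i(y) = ||y - A d_i(x)||` (where
#' `d_i` keeps only class-i coefficients) and the average coefficient
#' `S_i(y)` (sum of class-i coefficients divided by the class-i column
#' count; zeros count). The residual rule and the average rule are applied by
#' [predict_src()] and [predict_src_ave()] respectively.
#'
#' @param dict a [labeled_dictionary()].
#' @param y query vector.
#' @param settings a [solver_settings()].
#' @param code optional precomputed [solve_l1()] result for `y` against
#'   `dict$A` (skips the solve).
#' @return A list of class `class_scores` with named `residuals`, `averages`,
#'   `classes`, `predicted` (`NA` until a rule is applied) and the `code`.
#' @export
score_src <- function(dict, y, settings = solver_settings(), code = NULL) {
  stopifnot(inherits(dict, "labeled_dictionary"))
  y <- as.numeric(y)
  if (length(y) != nrow(dict$A))
    stop("query length does not match dictionary feature dimension")
  if (is.null(code)) {
    tau <- settings$tau %||%
      (settings$tau_scale * max(abs(crossprod(dict$A, y))))
    if (!is.finite(tau)) tau <- 0
    code <- solve_l1(sparse_problem(dict$A, y, tau = tau,
                                    tol = settings$tol,
                                    max_iter = settings$max_iter))
  }
  x <- if (inherits(code, "sparse_code")) code$x_hat else as.numeric(code)
  classes <- dict$classes
  K <- length(classes)
  residuals <- numeric(K)
  averages <- numeric(K)
  for (i in seq_len(K)) {
    idx <- which(dict$labels == classes[i])
    recon <- dict$A[, idx, drop = FALSE] %*% x[idx]
    residuals[i] <- sqrt(sum((y - recon)^2))
    averages[i] <- sum(x[idx]) / length(idx)
  }
  names(residuals) <- names(averages) <- classes
  structure(list(residuals = residuals, averages = averages,
                 classes = classes, predicted = NA, code = code),
            class = "class_scores")
}

#' Classify by minimal reconstruction residual (SRC rule)
#'
#' @param scores a `class_scores` object from [score_src()].
#' @return The class id with the smallest residual; ties go to the lowest
#'   class index.
#' @export
predict_src <- function(scores) {
  stopifnot(inherits(scores, "class_scores"))
  if (length(scores$residuals) == 0L) stop("empty scores")
  scores$classes[which.min(scores$residuals)]
}

#' Classify by maximal average coefficient (SRC-AVE rule)
#'
#' @param scores a `class_scores` object from [score_src()].
#' @return The class id with the largest average coefficient; ties go to the
#'   lowest class index.
#' @export
predict_src_ave <- function(scores) {
  stopifnot(inherits(scores, "class_scores"))
  if (length(scores$averages) == 0L) stop("empty scores")
  scores$classes[which.max(scores$averages)]
}

# ---------------------------------------------------------------------------
# Linear discriminant classifier with diagonal shrinkage
# ---------------------------------------------------------------------------

# Ledoit-Wolf shrinkage intensity toward the scaled identity, computed on
# within-class-centered samples Z (n x p, rows = samples).
ledoit_wolf_gamma <- function(Z) {
  n <- nrow(Z)
  p <- ncol(Z)
  S <- crossprod(Z) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2)
  if (d2 < 1e-300) return(1)
  row_norms2 <- rowSums(Z^2)
  b2bar <- sum(row_norms2^2) / n^2 - sum(S^2) / n
  gamma <- min(b2bar, d2) / d2
  min(1, max(0, gamma))
}

ldc_refit <- function(model) {
  p <- nrow(model$sums)
  K <- ncol(model$sums)
  n <- sum(model$counts)
  means <- sweep(model$sums, 2, model$counts, "/")
  scatter <- model$xx - means %*% (t(means) * model$counts)
  denom <- max(n - K, 1L)
  Sw <- scatter / denom
  mu <- sum(diag(Sw)) / p
  if (!is.finite(mu) || mu <= 0) mu <- 1
  Sigma <- (1 - model$gamma) * Sw + diag(model$gamma * mu, p)
  W <- solve(Sigma, means)
  priors <- model$counts / n
  model$means <- means
  model$pooled_cov <- Sigma
  model$priors <- priors
  model$W <- W
  model$const <- log(priors) - 0.5 * colSums(means * W)
  model
}

#' Fit a linear discriminant classifier with diagonal shrinkage
#'
#' Gaussian classes with class-specific means and a common covariance. The
#' pooled within-class covariance is shrunk toward a scaled identity,
#' `Sigma = (1 - gamma) * S_w + gamma * mean(diag(S_w)) * I`, which keeps the
#' model computable when features outnumber samples. By default `gamma` is
#' the Ledoit-Wolf analytic estimate from the within-class-centered training
#' samples.
#'
#' @param X training matrix, features x samples.
#' @param labels per-column class labels; every class needs at least one
#'   sample and at least two samples are required overall.
#' @param gamma shrinkage weight in `[0, 1]`, or `NULL` for the analytic
#'   estimate.
#' @return A list of class `ldc_model` with `means`, `pooled_cov`, `priors`,
#'   `gamma` and sufficient statistics enabling exact online updates.
#' @export
fit_ldc <- function(X, labels, gamma = NULL) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (n < 2L) stop("need at least two training samples")
  if (length(labels) != n) stop("labels length does not match sample count")
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(counts == 0L)) stop("every class needs at least one sample")
  p <- nrow(X)
  sums <- vapply(classes, function(cl)
    rowSums(X[, labels == cl, drop = FALSE]), numeric(p))
  sums <- matrix(sums, nrow = p)
  xx <- tcrossprod(X)
  if (is.null(gamma)) {
    means <- sweep(sums, 2, counts, "/")
    Zc <- X - means[, match(labels, classes), drop = FALSE]
    gamma <- ledoit_wolf_gamma(t(Zc))
  }
  stopifnot(gamma >= 0, gamma <= 1)
  model <- structure(list(classes = classes, counts = counts, sums = sums,
                          xx = xx, gamma = gamma),
                     class = "ldc_model")
  ldc_refit(model)
}

#' Add one labeled sample to a fitted LDC (exact online refit)
#'
#' Updates the sufficient statistics and recomputes means, pooled covariance
#' and discriminant weights exactly, as if the model had been refit from the
#' augmented training set. The shrinkage intensity estimated at the initial
#' fit is kept fixed.
#'
#' @param model an `ldc_model`.
#' @param y sample vector.
#' @param label its class label (must be one of the model's classes).
#' @return The updated model.
#' @export
update_ldc <- function(model, y, label) {
  stopifnot(inherits(model, "ldc_model"))
  i <- match(label, model$classes)
  if (is.na(i)) stop("unknown class id: ", label)
  y <- as.numeric(y)
  model$counts[i] <- model$counts[i] + 1L
  model$sums[, i] <- model$sums[, i] + y
  model$xx <- model$xx + tcrossprod(y)
  ldc_refit(model)
}

#' Predict with a linear discriminant classifier
#'
#' Evaluates `g_i(y) = log P_i - 0.5 * t(mu_i) Sigma^-1 mu_i +
#' t(mu_i) Sigma^-1 y` for every class and returns the argmax.
#'
#' @param model an `ldc_model` from [fit_ldc()].
#' @param y query vector.
#' @return The class id with the largest discriminant; ties go to the lowest
#'   class index.
#' @export
predict_ldc <- function(model, y) {
  stopifnot(inherits(model, "ldc_model"))
  y <- as.numeric(y)
  if (length(y) != nrow(model$means)) stop("query dimension mismatch")
  g <- model$const + as.numeric(crossprod(model$W, y))
  model$classes[which.max(g)]
}

#' @export
print.ldc_model <- function(x, ...) {
  cat("<ldc_model> ", nrow(x$means), " features, classes: ",
      paste(x$classes, collapse = ", "), "; gamma = ",
      format(x$gamma, digits = 3), "\n", sep = "")
  invisible(x)
}
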