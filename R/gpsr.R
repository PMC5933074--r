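#' Solver settings for the l1 sparse coding problem
#'
#' Bundles the tunables of the gradient-projection solver. The penalty
#' weight is data-dependent by default: `tau = tau_scale * max(abs(t(A) %*% y))`,
#' the usual scaling heuristic for gradient-projection sparse reconstruction.
#'
#' @param tau fixed l1 penalty weight, or `NULL` to derive it from
#'   `tau_scale` and the data (the default).
#' @param tau_scale multiplier on `max(abs(t(A) %*% y))` used when `tau` is
#'   `NULL`.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap.
#' @param zero_tol coefficients with absolute value below this are truncated
#'   to exact zeros when reporting sparsity.
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(tau = NULL, tau_scale = 0.1, tol = 1e-6,
                            max_iter = 1000L, zero_tol = 1e-12) {
  stopifnot(is.null(tau) || (is.numeric(tau) && tau >= 0),
            tau_scale >= 0, tol > 0, max_iter >= 1)
  structure(list(tau = tau, tau_scale = tau_scale, tol = tol,
                 max_iter = as.integer(max_iter), zero_tol = zero_tol),
            class = "solver_settings")
}

#' Define an l1-regularized sparse coding problem
#'
#' Represents the problem `min_x 0.5 * ||y - A x||^2 + tau * ||x||_1`, the
#' penalized (Lagrangian) form of basis-pursuit sparse coding. Queries are
#' coded against a dictionary whose columns are training samples.
#'
#' @param A dictionary matrix, features x samples.
#' @param y query vector (length `nrow(A)`).
#' @param tau l1 penalty weight (>= 0); default `0.1 * max(abs(t(A) %*% y))`.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return A list of class `sparse_problem`.
#' @export
sparse_problem <- function(A, y, tau = NULL, tol = 1e-6, max_iter = 1000L) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  if (!is.numeric(A)) stop("dictionary must be numeric")
  if (ncol(A) < 1L) stop("dictionary must have at least one column")
  if (length(y) != nrow(A))
    stop("query length (", length(y), ") does not match dictionary feature ",
         "dimension (", nrow(A), ")")
  if (!all(is.finite(A))) stop("non-finite entries in dictionary")
  if (!all(is.finite(y))) stop("non-finite entries in query")
  if (!is.null(tau) && (!is.numeric(tau) || length(tau) != 1L || tau < 0))
    stop("tau must be a single nonnegative number")
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(A = A, y = y, tau = tau, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "sparse_problem")
}

#' Solve an l1 sparse coding problem by gradient projection
#'
#' Minimizes `0.5 * ||y - A x||^2 + tau * ||x||_1` by gradient projection on
#' the positive split `x = u - v` with Barzilai-Borwein step proposals and an
#' exact (closed-form) line search, so the recorded objective trace is
#' non-increasing. Deterministic given identical inputs.
#'
#' @param problem a [sparse_problem()].
#' @param x0 optional warm-start coefficient vector.
#' @return A list of class `sparse_code` with elements `x_hat` (coefficients,
#'   entries below `1e-12` truncated to zero), `objective_trace`, `n_iter`,
#'   `converged`, and `tau` (the penalty actually used).
#' @examples
#' A <- diag(2); y <- c(3, 0)
#' solve_l1(sparse_problem(A, y, tau = 1))$x_hat  # soft threshold: (2, 0)
#' @export
solve_l1 <- function(problem, x0 = NULL) {
  stopifnot(inherits(problem, "sparse_problem"))
  A <- problem$A
  y <- problem$y
  m <- ncol(A)
  tau <- problem$tau
  if (is.null(tau)) tau <- 0.1 * max(abs(crossprod(A, y)))
  if (!is.finite(tau)) tau <- 0
  res <- if (m < nrow(A)) {
    gpsr_gram_cpp(crossprod(A), as.numeric(crossprod(A, y)), sum(y^2),
                  tau, problem$tol, problem$max_iter, x0)
  } else {
    gpsr_mat_cpp(A, y, tau, problem$tol, problem$max_iter, x0)
  }
  new_sparse_code(res, tau, zero_tol = 1e-12)
}

new_sparse_code <- function(res, tau, zero_tol = 1e-12) {
  x <- as.numeric(res$x)
  x[abs(x) < zero_tol] <- 0
  structure(list(x_hat = x,
                 objective_trace = as.numeric(res$objective_trace),
                 n_iter = res$n_iter,
                 converged = res$converged,
                 tau = tau),
            class = "sparse_code")
}

#' @export
print.sparse_code <- function(x, ...) {
  cat("<sparse_code> ", length(x$x_hat), " coefficients, ",
      sum(x$x_hat != 0), " nonzero; ", x$n_iter, " iterations (",
      if (x$converged) "converged" else "iteration cap reached", "), tau = ",
      format(x$tau, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Restrict a sparse code to one class
#'
#' Returns the class-selector vector: equal to the estimated coefficients on
#' dictionary columns labeled `class_id`, zero elsewhere. Summing the result
#' over all classes reconstructs the full coefficient vector.
#'
#' @param code a [solve_l1()] result (or any numeric coefficient vector).
#' @param labels per-column class labels, same length as the coefficients.
#' @param class_id the class to keep.
#' @return Numeric vector of the same length as the coefficients.
#' @export
split_by_class <- function(code, labels, class_id) {
  x <- if (inherits(code, "sparse_code")) code$x_hat else as.numeric(code)
  if (length(labels) != length(x))
    stop("labels length (", length(labels), ") does not match coefficient ",
         "length (", length(x), ")")
  if (!class_id %in% labels) stop("unknown class id: ", class_id)
  out <- numeric(length(x))
  keep <- labels == class_id
  out[keep] <- x[keep]
  out
}
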