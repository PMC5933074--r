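# Independent oracles and small fixture builders used across the suite.
# The coordinate-descent lasso below is the reference solver for the
# gradient-projection implementation: same objective, different algorithm,
# run to a much tighter tolerance.

cd_lasso <- function(A, y, tau, tol = 1e-14, max_sweeps = 50000) {
  m <- ncol(A)
  x <- numeric(m)
  Aty <- as.numeric(crossprod(A, y))
  G <- crossprod(A)
  d <- diag(G)
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(m)) {
      if (d[j] == 0) next
      rho <- Aty[j] - sum(G[j, ] * x) + d[j] * x[j]
      xn <- sign(rho) * max(abs(rho) - tau, 0) / d[j]
      delta <- max(delta, abs(xn - x[j]))
      x[j] <- xn
    }
    if (delta < tol) break
  }
  x
}

lasso_objective <- function(A, y, x, tau) {
  0.5 * sum((y - A %*% x)^2) + tau * sum(abs(x))
}

# direct (independent) causal convolution, truncated to the input length
conv_hrf_for_test <- function(x, h) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    j <- seq_len(min(t, length(h)))
    out[t] <- sum(h[j] * x[t - j + 1])
  }
  out
}

# class_scores stub for rule-level tests
make_scores <- function(averages, residuals = rep(1, length(averages)),
                        classes = seq_along(averages), predicted = NA) {
  structure(list(residuals = residuals, averages = averages,
                 classes = classes, predicted = predicted, code = NULL),
            class = "class_scores")
}

# Well-separated K-class toy problem: class templates plus isotropic noise,
# columns z-scored like the real pipeline's patterns.
make_toy_problem <- function(K = 3, p = 60, n_per_class = 15, n_test = 30,
                             sep = 3, noise = 1, seed = 1) {
  withr::with_seed(seed, {
    templates <- matrix(rnorm(p * K, sd = sep), p, K)
    tr_lab <- rep(seq_len(K), each = n_per_class)
    A <- templates[, tr_lab] + matrix(rnorm(p * length(tr_lab), sd = noise),
                                      p)
    te_lab <- sample(seq_len(K), n_test, replace = TRUE)
    Y <- templates[, te_lab] + matrix(rnorm(p * n_test, sd = noise), p)
    list(train = labeled_dictionary(apply(A, 2, function(v) (v - mean(v)) / sd(v)),
                                    tr_lab),
         test = apply(Y, 2, function(v) (v - mean(v)) / sd(v)),
         test_labels = te_lab)
  })
}

# Small, fast simulated dataset (short paradigm, small grid) for pipeline
# and stream tests.
make_small_dataset <- function(seed = 1, cnr = 0.2, grid = 24, group = 1,
                               motion = FALSE) {
  par1 <- make_paradigm(blocks_per_task = 2, task_seconds = 20,
                        rest_seconds = 10, seed = seed)
  par2 <- make_paradigm(blocks_per_task = 2, task_seconds = 20,
                        rest_seconds = 10, seed = seed + 50L)
  smap1 <- default_source_map(grid, "standard", n_sources = 9, seed = seed)
  smap2 <- default_source_map(grid,
                              if (group == 2) "shifted" else "standard",
                              n_sources = 9, seed = seed)
  xf <- subject_transforms(9, seed = seed, grid = grid)
  list(subject = 1, cnr = cnr, group = group,
       train = generate_run(par1, smap1, cnr, xf, seed = seed,
                            motion = motion, subject_id = 1, group = group),
       test = generate_run(par2, smap2, cnr, xf, seed = seed + 1000L,
                           motion = motion, subject_id = 1, group = group))
}

small_config <- function(k = 80, L = 5) {
  cfg <- default_config()
  cfg$features$k <- k
  cfg$ensemble$L <- L
  cfg
}
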