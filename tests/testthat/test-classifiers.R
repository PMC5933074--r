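# Supervised decision rules: residual SRC, average-coefficient SRC-AVE, LDC

test_that("score_src computes residuals and class averages", {
  # orthonormal two-class dictionary: class 1 represents e1 exactly
  A <- diag(2)
  dict <- labeled_dictionary(A, c(1, 2))
  sc <- score_src(dict, c(1, 0), solver_settings(tau = 1e-10))
  expect_equal(unname(sc$residuals), c(0, 1), tolerance = 1e-6)
  expect_identical(predict_src(sc), 1)

  # averages include zero coefficients: divide by the class column count
  dict4 <- labeled_dictionary(matrix(rnorm(12, sd = 1), 3, 4), c(1, 1, 2, 2))
  sc4 <- score_src(dict4, rnorm(3), code = c(0.5, 0.3, -0.1, 0.2))
  expect_equal(unname(sc4$averages), c(0.4, 0.05))

  expect_error(score_src(dict, c(1, 2, 3)), "dimension")
})

test_that("average-rule consistency and residual bound hold on random codes", {
  withr::with_seed(21, {
    for (i in 1:15) {
      p <- 10
      n <- 12
      labels <- sample(1:3, n, replace = TRUE)
      while (length(unique(labels)) < 3)
        labels <- sample(1:3, n, replace = TRUE)
      dict <- labeled_dictionary(matrix(rnorm(p * n), p), labels)
      y <- rnorm(p)
      sc <- score_src(dict, y)
      counts <- table(factor(dict$labels, levels = dict$classes))
      # sum over classes of count * average == sum of all coefficients
      expect_equal(sum(as.numeric(counts) * sc$averages),
                   sum(sc$code$x_hat), tolerance = 1e-10)
      # triangle inequality sanity bound on every residual
      for (k in seq_along(dict$classes)) {
        recon <- dict$A %*% split_by_class(sc$code, dict$labels,
                                           dict$classes[k])
        expect_lte(sc$residuals[k],
                   sqrt(sum(y^2)) + sqrt(sum(recon^2)) + 1e-10)
      }
    }
  })
})

test_that("prediction rules take the extremum with ties to the lowest class", {
  expect_identical(predict_src(make_scores(c(1, 2, 3),
                                           residuals = c(0.2, 0.5, 0.9))), 1L)
  expect_identical(predict_src(make_scores(1:3, residuals = rep(0.4, 3))), 1L)
  expect_identical(predict_src_ave(make_scores(c(0.4, 0.05, -0.1))), 1L)
  expect_identical(predict_src_ave(make_scores(c(0, 0))), 1L)
  # brute-force agreement on random score sets
  withr::with_seed(31, {
    for (i in 1:1000) {
      K <- sample(2:6, 1)
      res <- runif(K)
      avg <- rnorm(K)
      sc <- make_scores(avg, residuals = res, classes = seq_len(K) + 10L)
      bf_min <- (seq_len(K))[res == min(res)][1]
      bf_max <- (seq_len(K))[avg == max(avg)][1]
      expect_identical(predict_src(sc), bf_min + 10L)
      expect_identical(predict_src_ave(sc), bf_max + 10L)
    }
  })
  expect_error(predict_src(make_scores(numeric(0), residuals = numeric(0),
                                       classes = integer(0))), "empty")
})

test_that("SRC-AVE recovers the generating class on a separable toy problem", {
  toy <- make_toy_problem(n_test = 200, seed = 6)
  preds <- vapply(seq_len(ncol(toy$test)), function(m)
    predict_src_ave(score_src(toy$train, toy$test[, m])), integer(1))
  expect_gte(mean(preds == toy$test_labels), 0.95)
})

test_that("fit_ldc recovers degenerate and Gaussian geometry", {
  # two point classes: means exact, scatter zero, shrinkage forced spherical
  X <- cbind(c(1, 0), c(1, 0), c(-1, 0), c(-1, 0))
  mod <- fit_ldc(X, c(1, 1, 2, 2))
  expect_equal(unname(mod$means), cbind(c(1, 0), c(-1, 0)))
  expect_identical(mod$gamma, 1)
  expect_equal(mod$pooled_cov, diag(2))
  expect_identical(predict_ldc(mod, c(0.9, 0.3)), 1)
  expect_identical(predict_ldc(mod, c(-0.9, 0.3)), 2)

  # gamma = 1 reduces to the prior-weighted nearest-mean rule
  withr::with_seed(41, {
    X <- matrix(rnorm(5 * 60), 5)
    labels <- rep(1:3, each = 20)
    X <- X + outer(rep(1, 5), labels)
    mod1 <- fit_ldc(X, labels, gamma = 1)
    mu <- mod1$means
    sph <- mean(diag(mod1$pooled_cov))
    for (i in 1:20) {
      y <- rnorm(5, mean = 2)
      g <- log(mod1$priors) - 0.5 * colSums(mu^2) / sph +
        as.numeric(crossprod(mu, y)) / sph
      expect_identical(predict_ldc(mod1, y), (1:3)[which.max(g)])
    }
  })

  # parameter recovery: class means within 3 SE of the generating means
  withr::with_seed(43, {
    n <- 400
    labels <- rep(1:2, each = n / 2)
    truth <- cbind(c(1, -1, 0), c(-1, 1, 0.5))
    X <- truth[, labels] + matrix(rnorm(3 * n), 3)
    mod <- fit_ldc(X, labels)
    se <- 1 / sqrt(n / 2)
    expect_true(all(abs(mod$means - truth) < 3 * se))
    expect_equal(sum(mod$priors), 1, tolerance = 1e-12)
  })

  expect_error(fit_ldc(matrix(1:2, 2, 1), 1), "two training samples")
})

test_that("predict_ldc matches a brute-force Gaussian density ratio", {
  withr::with_seed(47, {
    p <- 4
    labels <- rep(1:3, times = c(30, 50, 20))
    X <- matrix(rnorm(p * length(labels)), p) +
      cbind(c(2, 0, 0, 0), c(0, 2, 0, 0), c(0, 0, 2, 0))[, labels]
    mod <- fit_ldc(X, labels)
    Sinv <- solve(mod$pooled_cov)
    for (i in 1:500) {
      y <- rnorm(p, sd = 2)
      # log posterior up to a constant, evaluated the long way
      g <- vapply(1:3, function(k) {
        mu <- mod$means[, k]
        log(mod$priors[k]) - 0.5 * t(y - mu) %*% Sinv %*% (y - mu)
      }, numeric(1))
      expect_identical(predict_ldc(mod, y), (1:3)[which.max(g)])
    }
  })
})

test_that("exact online LDC update equals a fresh refit", {
  withr::with_seed(53, {
    X <- matrix(rnorm(6 * 40), 6)
    labels <- rep(1:2, each = 20)
    mod <- fit_ldc(X, labels)
    y1 <- rnorm(6)
    y2 <- rnorm(6)
    mod <- update_ldc(mod, y1, 2)
    mod <- update_ldc(mod, y2, 1)
    ref <- fit_ldc(cbind(X, y1, y2), c(labels, 2, 1), gamma = mod$gamma)
    expect_equal(mod$means, ref$means, tolerance = 1e-12)
    expect_equal(mod$pooled_cov, ref$pooled_cov, tolerance = 1e-12)
    expect_equal(mod$priors, ref$priors, tolerance = 1e-12)
  })
  expect_error(update_ldc(fit_ldc(diag(2), c(1, 2)), c(1, 1), 9),
               "unknown class")
})

test_that("dictionaries validate input and grow by appending", {
  expect_error(labeled_dictionary(matrix(c(1, NA), 1), c(1, 2)), "non-finite")
  expect_error(labeled_dictionary(diag(2), 1), "labels length")
  dict <- labeled_dictionary(diag(3), c(1, 2, 2))
  grown <- append_sample(dict, c(5, 7, 9), 1, normalize = FALSE)
  expect_identical(ncol(grown$A), 4L)
  expect_identical(grown$labels, c(1, 2, 2, 1))
  # normalized append z-scores the column; re-application is idempotent
  g2 <- append_sample(dict, c(5, 7, 9), 1)
  expect_equal(mean(g2$A[, 4]), 0, tolerance = 1e-12)
  expect_equal(sd(g2$A[, 4]), 1, tolerance = 1e-12)
  expect_equal(append_sample(dict, g2$A[, 4], 1)$A[, 4], g2$A[, 4],
               tolerance = 1e-12)
})
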