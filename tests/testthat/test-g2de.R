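test_that("component value matches hand evaluations and is linear in w", {
  expect_equal(g2de_component(1, rep(0, 3), diag(3), rep(0, 3)), 1)
  expect_equal(g2de_component(1, 0, matrix(4), 2), 0.5 * exp(-0.5),
               tolerance = 1e-12)
  expect_equal(g2de_component(3.7, 0, matrix(4), 2),
               3.7 * g2de_component(1, 0, matrix(4), 2), tolerance = 1e-12)
  expect_error(g2de_component(1, c(0, 0), matrix(c(1, 2, 2, 1), 2), c(0, 0)),
               "positive definite")
})

test_that("mixture density peaks, symmetries and unit mass hold", {
  m1 <- structure(list(K = 1L, d = 1L, weights = 1, means = matrix(0),
                       covariances = list(matrix(1))), class = "g2de")
  expect_equal(g2de_density(m1, 0), 1 / sqrt(2 * pi), tolerance = 1e-12)

  m2 <- structure(list(K = 2L, d = 1L, weights = c(2, 2),
                       means = matrix(c(-1.5, 1.5)),
                       covariances = list(matrix(0.7), matrix(0.7))),
                  class = "g2de")
  x <- seq(0.1, 4, by = 0.3)
  expect_equal(g2de_density(m2, matrix(x)), g2de_density(m2, matrix(-x)),
               tolerance = 1e-12)

  # random K = 3, d = 2 model: quadrature mass = 1
  set.seed(9)
  covs <- lapply(1:3, function(i) { a <- matrix(rnorm(4), 2); crossprod(a) + diag(2) })
  m3 <- structure(list(K = 3L, d = 2L, weights = runif(3, 0.5, 2),
                       means = matrix(rnorm(6), 3, 2), covariances = covs),
                  class = "g2de")
  gx <- seq(-12, 12, length.out = 241)
  h <- diff(gx[1:2])
  grid <- as.matrix(expand.grid(gx, gx))
  mass <- sum(g2de_density(m3, grid)) * h^2
  expect_equal(mass, 1, tolerance = 1e-6)

  expect_error(g2de_density(m1, c(0, 0)), "dimension")
})

test_that("parameter count formula equals the direct enumeration", {
  expect_identical(g2de_param_count(2, 5), 42L)
  expect_identical(g2de_param_count(1, 1), 3L)
  for (K in 1:10) for (d in 1:10) {
    direct <- K * (1 + d + d * (d + 1) / 2)  # weight + center + covariance
    expect_identical(g2de_param_count(K, d), as.integer(direct))
  }
})

test_that("K = 1 fit equals the closed-form Gaussian MLE", {
  set.seed(10)
  x <- matrix(rnorm(600), ncol = 3)
  fit <- fit_g2de(x, K = 1, n_restarts = 1, rng_seed = 1)
  expect_equal(fit$means[1, ], colMeans(x), tolerance = 1e-9,
               ignore_attr = TRUE)
  S <- cov(x) * (nrow(x) - 1) / nrow(x)
  expect_equal(fit$covariances[[1]], S + diag(1e-6 * sum(diag(S)) / 3 + 1e-12, 3),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("EM recovers a planted 2-component mixture and is monotone", {
  mix <- draw_known_mixture(5000, seed = 21)
  fit <- fit_g2de(mix$x, K = 2, n_restarts = 5, rng_seed = 21)
  # components sorted by weight: cluster 0 = majority = generating component 1
  expect_lt(max(abs(fit$means - mix$means)), 0.15)
  w <- fit$weights / sum(fit$weights)
  expect_lt(max(abs(w - mix$weights)), 0.03)
  expect_lt(max(abs(fit$covariances[[1]] - diag(2))), 0.2)
  expect_lt(max(abs(fit$covariances[[2]] - diag(2))), 0.2)
  labs <- assign_clusters(fit, mix$x)
  expect_gte(mean(labs == mix$labels), 0.98)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6 * abs(fit$loglik)))
})

test_that("fit is invariant to row order up to component relabeling", {
  mix <- draw_known_mixture(800, seed = 22)
  fit <- fit_g2de(mix$x, K = 2, n_restarts = 4, rng_seed = 5)
  perm <- sample(nrow(mix$x))
  fitp <- fit_g2de(mix$x[perm, ], K = 2, n_restarts = 4, rng_seed = 5)
  # weight-sorted components should agree closely between the two runs
  expect_equal(fitp$means, fit$means, tolerance = 1e-3)
  expect_equal(fitp$weights / sum(fitp$weights),
               fit$weights / sum(fit$weights), tolerance = 1e-3)
})

test_that("cluster assignment uses posteriors with index tie-break", {
  m <- structure(list(K = 2L, d = 1L, weights = c(1, 1),
                      means = matrix(c(-2, 2)),
                      covariances = list(matrix(1), matrix(1))),
                 class = "g2de")
  expect_identical(assign_clusters(m, matrix(-2)), 0L)
  expect_identical(assign_clusters(m, matrix(2)), 1L)
  # exactly equidistant between identical components: lower index wins
  expect_identical(assign_clusters(m, matrix(0)), 0L)
})

test_that("EM log-likelihood agrees with an independent full-covariance fit", {
  suppressPackageStartupMessages(library(mclust))
  mix <- draw_known_mixture(2000, seed = 23)
  fit <- fit_g2de(mix$x, K = 2, n_restarts = 5, rng_seed = 3)
  mc <- mclust::Mclust(mix$x, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("model serialization round-trips through text", {
  mix <- draw_known_mixture(500, seed = 24)
  fit <- fit_g2de(mix$x, K = 2, n_restarts = 2, rng_seed = 1)
  path <- withr::local_tempfile(fileext = ".txt")
  write_g2de(fit, path)
  fit2 <- read_g2de(path)
  q <- mix$x[1:20, ]
  expect_equal(g2de_density(fit2, q), g2de_density(fit, q), tolerance = 1e-12)
  expect_identical(assign_clusters(fit2, q), assign_clusters(fit, q))
})

test_that("degenerate sample sizes and collapses raise errors", {
  expect_error(fit_g2de(matrix(rnorm(8), 4, 2), K = 2), "n >= K")
})

test_that("BIC helper prefers the generating component count", {
  mix <- draw_known_mixture(2500, w2 = 0.3, seed = 25)
  tab <- g2de_bic(mix$x, K_range = 1:3, n_restarts = 3, rng_seed = 2)
  expect_equal(tab$K[which.min(tab$bic)], 2)
})
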