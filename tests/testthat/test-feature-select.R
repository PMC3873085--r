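test_that("min-max normalization maps examples, constants and round trips", {
  x <- matrix(c(0, 5, 10, 3, 3, 3), ncol = 2)
  nm <- min_max_normalize(x)
  expect_equal(nm$matrix[, 1], c(0, 0.5, 1))
  expect_equal(nm$matrix[, 2], c(0, 0, 0))   # constant column rule
  # round trip on the non-constant column
  back <- invert_min_max(nm$matrix, nm)
  expect_equal(back[, 1], x[, 1], tolerance = 1e-12)
  # idempotence
  nm2 <- min_max_normalize(nm$matrix)
  expect_equal(nm2$matrix, nm$matrix, tolerance = 1e-12)
})

test_that("recorded min/max project new data onto the same scale", {
  set.seed(51)
  x <- matrix(runif(60, 2, 9), ncol = 3)
  nm <- min_max_normalize(x)
  expect_equal(apply_min_max(x, nm), nm$matrix, tolerance = 1e-12)
  expect_equal(apply_min_max(matrix(c(2, 5, 9), 1),
                             list(mins = c(2, 2, 2), maxs = c(9, 9, 9))),
               matrix(c(0, 3 / 7, 1), 1), tolerance = 1e-12)
})

test_that("KMO equals 0.5 for any correlated pair and detects block structure", {
  # d = 2: the partial correlation equals the correlation, so KMO = 1/2 exactly
  for (r in c(-0.8, 0.1, 0.65)) {
    R <- matrix(c(1, r, r, 1), 2)
    expect_equal(kmo_statistic(R), 0.5, tolerance = 1e-12)
  }

  # strong within-block correlation across 6 variables: adequate sampling
  set.seed(52)
  f1 <- rnorm(2000); f2 <- rnorm(2000)
  x <- cbind(f1 + rnorm(2000, sd = 0.6), f1 + rnorm(2000, sd = 0.6),
             f1 + rnorm(2000, sd = 0.6), f2 + rnorm(2000, sd = 0.6),
             f2 + rnorm(2000, sd = 0.6), f2 + rnorm(2000, sd = 0.6))
  k <- kmo_statistic(x)
  expect_gt(k, 0.5)
  expect_lte(k, 1)

  # independent noise: near 0.5, bounded in [0, 1], order-invariant
  set.seed(53)
  noise <- matrix(rnorm(5000 * 4), ncol = 4)
  k0 <- kmo_statistic(noise)
  expect_lt(abs(k0 - 0.5), 0.05)
  expect_equal(kmo_statistic(noise[, 4:1]), k0, tolerance = 1e-12)
})

test_that("Bartlett sphericity matches its closed form and edge cases", {
  expect_error(bartlett_sphericity(diag(3)), "sample size")
  res <- bartlett_sphericity(diag(3), n = 100)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(54)
  f <- rnorm(1000)
  x <- cbind(f + rnorm(1000, sd = 0.3), f + rnorm(1000, sd = 0.3))
  res <- bartlett_sphericity(x)
  expect_lt(res$p_value, 0.001)
  # closed form check
  R <- cor(x)
  expect_equal(res$statistic, -(1000 - 1 - 9 / 6) * log(det(R)),
               tolerance = 1e-12)
  expect_gte(res$statistic, 0)
})

test_that("factor retention applies the strict eigenvalue rule", {
  # identity correlation: every eigenvalue exactly 1, nothing retained
  ret <- retain_factors(diag(4))
  expect_identical(ret$n_factors, 0L)
  expect_identical(ncol(ret$loadings), 0L)

  # 2 x 2 with r = 0.8: eigenvalues 1 +/- r, one factor
  ret <- retain_factors(matrix(c(1, 0.8, 0.8, 1), 2))
  expect_equal(ret$eigenvalues, c(1.8, 0.2), tolerance = 1e-12)
  expect_identical(ret$n_factors, 1L)
  # loadings = eigenvector * sqrt(eigenvalue)
  expect_equal(abs(ret$loadings[, 1]), rep(sqrt(1.8 / 2), 2), tolerance = 1e-12)

  # trace conservation
  set.seed(55)
  x <- matrix(rnorm(600), ncol = 6)
  R <- cor(x)
  expect_equal(sum(retain_factors(R)$eigenvalues), 6, tolerance = 1e-10)
})

test_that("varimax preserves communalities and leaves simple structure alone", {
  # m = 1: no rotational freedom
  L1 <- matrix(c(0.9, 0.3, 0.5), ncol = 1)
  expect_equal(varimax_rotate(L1)$loadings, L1)

  # perfect simple structure: unchanged up to column permutation and sign
  L <- rbind(c(0.9, 0), c(0.85, 0), c(0, 0.8), c(0, 0.75))
  rot <- varimax_rotate(L)
  expect_equal(sort(round(abs(rot$loadings[rot$loadings != 0]), 6)),
               sort(round(abs(L[L != 0]), 6)), tolerance = 1e-6)

  set.seed(56)
  x <- matrix(rnorm(3000), ncol = 6)
  x[, 1:3] <- x[, 1:3] + rnorm(500)
  x[, 4:6] <- x[, 4:6] + rnorm(500)
  ret <- retain_factors(cor(x))
  rot <- varimax_rotate(ret$loadings)
  # orthogonality of the rotation matrix
  expect_equal(crossprod(rot$rotation), diag(ncol(rot$rotation)),
               tolerance = 1e-10)
  # row communalities preserved
  expect_equal(rowSums(rot$loadings^2), rowSums(ret$loadings^2),
               tolerance = 1e-10)
})

test_that("loading-cutoff selection keeps only strong features", {
  L <- matrix(c(0.9, 0.1), ncol = 1,
              dimnames = list(c("f1", "f2"), NULL))
  expect_identical(select_features(L, 0.4), "f1")
  expect_warning(sel <- select_features(L, 1.01), "cutoff")
  expect_length(sel, 0)
})

test_that("the planted dosage-factor fixture selects exactly the dosage features", {
  x <- simulate_factor_fixture(n = 8000, rng_seed = 57)
  fs <- run_factor_selection(x, cutoff = 0.4)
  dosage_cols <- grep("_dosage_mg$", exposure_feature_names(), value = TRUE)
  expect_setequal(fs$selected_features, dosage_cols)
  expect_identical(fs$n_factors, 2L)
  expect_gt(fs$kmo, 0.5)
  expect_lt(fs$bartlett_p, 0.001)
  # selection order follows the original columns
  expect_identical(fs$selected_features,
                   exposure_feature_names()[exposure_feature_names() %in%
                                              fs$selected_features])
})

test_that("zero-variance columns are excluded and reported", {
  set.seed(58)
  x <- cbind(matrix(rnorm(300), ncol = 3), zero = 0)
  colnames(x) <- c("a", "b", "c", "zero")
  expect_warning(fs <- run_factor_selection(x, warn_adequacy = FALSE),
                 "zero-variance")
  expect_identical(fs$dropped, "zero")
  expect_false("zero" %in% fs$selected_features)
})
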