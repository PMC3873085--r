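# Relaxed variable kernel density estimation (RVKDE).
#
# One isotropic Gaussian kernel per training sample, with a per-sample
# bandwidth proportional to the sample's k-nearest-neighbour radius:
#
#   f(v) = (1/n) * sum_i (1 / (sqrt(2*pi) * sigma_i))^d
#                  * exp(-||v - s_i||^2 / (2 * sigma_i^2))
#
#   sigma_i = beta * R(s_i) * sqrt(pi) / ((k+1) * Gamma(d/2 + 1))^(1/d)
#
# where R(s_i) is the distance from s_i to its k-th nearest other training
# sample.  beta and k are smoothing hyper-parameters (cross-validated or
# user-set).  Exact duplicate samples — ubiquitous in claims-style exposure
# matrices, where non-utilizers share the all-zero vector — give R = 0 and
# an undefined kernel; bandwidths are floored (see fit_rvkde).

# squared Euclidean cross-distances, q x n, computed in blocks so that an
# n x n matrix is never materialized for large n
cross_dist2 <- function(queries, samples) {
  qs <- rowSums(queries^2)
  ss <- rowSums(samples^2)
  d2 <- outer(qs, ss, `+`) - 2 * tcrossprod(queries, samples)
  d2[d2 < 0] <- 0
  d2
}

#' k-nearest-neighbour radius of one training sample
#'
#' Distance from sample `i` to its `k`-th nearest *other* training sample
#' (equivalently, the maximum distance to its `k` nearest neighbours).  Ties
#' in distance are immaterial for the radius value; neighbour order among
#' ties follows sample index.
#'
#' @param samples n x d numeric matrix.
#' @param i sample index.
#' @param k neighbour count, `1 <= k <= n - 1`.
#' @return Positive (or zero, for duplicated points) scalar radius.
#' @export
knn_radius <- function(samples, i, k) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2) stop("at least two samples are required", call. = FALSE)
  if (k < 1 || k >= n)
    stop(sprintf("k must satisfy 1 <= k <= n - 1 (k = %d, n = %d)", k, n),
         call. = FALSE)
  d2 <- cross_dist2(samples[i, , drop = FALSE], samples)[1, -i]
  sqrt(sort(d2, partial = k)[k])
}

#' Per-sample bandwidth from the k-NN radius
#'
#' `sigma = beta * R * sqrt(pi) / ((k + 1) * Gamma(d/2 + 1))^(1/d)`.
#' The radius of a d-ball holding k+1 points at uniform density enters
#' through the denominator, so the kernel mass tracks local sampling
#' density; `beta` is a global smoothing multiplier.
#'
#' @param R k-NN radius (non-negative).
#' @param k neighbour count.
#' @param d dimension.
#' @param beta smoothing multiplier.
#' @param floor lower bound applied to the result (default 0 = no floor).
#' @return Bandwidth sigma.
#' @export
rvkde_bandwidth <- function(R, k, d, beta, floor = 0) {
  stopifnot(R >= 0, k >= 1, d >= 1, beta > 0)
  sigma <- beta * R * sqrt(pi) / ((k + 1) * gamma(d / 2 + 1))^(1 / d)
  pmax(sigma, floor)
}

#' Fit an RVKDE model
#'
#' Computes every sample's k-NN radius (in blocks; no n x n matrix is ever
#' held), converts radii to bandwidths, and floors degenerate bandwidths.
#' The floor is `max(eps_abs * diag, eps_rel * median positive bandwidth)`
#' where `diag` is the length of the bounding-box diagonal of the samples —
#' duplicates (zero radius) then carry a very narrow but finite kernel
#' instead of a delta spike.
#'
#' @param samples n x d numeric matrix.
#' @param k neighbour count (default 10); requires `n >= k + 1`.
#' @param beta smoothing multiplier (default 1).
#' @param eps_abs absolute floor as a fraction of the feature-space diagonal.
#' @param eps_rel floor relative to the median positive bandwidth.
#' @param block rows per block in the radius computation.
#' @return Object of class `rvkde`: list with `samples`, `bandwidths`, `k`,
#'   `beta`, `d`, `sigma_floor`.
#' @export
fit_rvkde <- function(samples, k = 10, beta = 1,
                      eps_abs = 1e-6, eps_rel = 1e-3, block = 1024L) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  n <- nrow(samples); d <- ncol(samples)
  if (n <= k)
    stop(sprintf("need n >= k + 1 samples (n = %d, k = %d)", n, k),
         call. = FALSE)

  radii <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- cross_dist2(samples[idx, , drop = FALSE], samples)
    # exclude self-distance before taking the k-th order statistic
    d2[cbind(seq_along(idx), idx)] <- Inf
    radii[idx] <- sqrt(apply(d2, 1, function(z) sort(z, partial = k)[k]))
  }

  sigma <- rvkde_bandwidth(radii, k, d, beta)
  span <- apply(samples, 2, function(x) diff(range(x)))
  diag_len <- sqrt(sum(span^2))
  med_pos <- stats::median(sigma[sigma > 0])
  if (!is.finite(med_pos)) med_pos <- 0
  floor_val <- max(eps_abs * diag_len, eps_rel * med_pos, .Machine$double.eps)
  sigma <- pmax(sigma, floor_val)

  structure(list(samples = samples, bandwidths = sigma, k = k, beta = beta,
                 d = d, sigma_floor = floor_val),
            class = "rvkde")
}

rvkde_density_block <- function(model, queries, drop_self = FALSE) {
  n <- nrow(model$samples)
  d2 <- cross_dist2(queries, model$samples)
  if (drop_self) {
    # queries are the training samples themselves, in order
    d2[cbind(seq_len(nrow(queries)), seq_len(nrow(queries)))] <- Inf
  }
  coef <- (1 / (sqrt(2 * pi) * model$bandwidths))^model$d
  kernels <- exp(-sweep(d2, 2, 2 * model$bandwidths^2, `/`))
  denom <- if (drop_self) n - 1 else n
  as.vector(kernels %*% coef) / denom
}

#' Evaluate an RVKDE density
#'
#' Literal evaluation of the per-sample Gaussian mixture: equal 1/n weights,
#' isotropic kernels, per-sample bandwidths.
#'
#' @param model an [fit_rvkde()] model.
#' @param v query: length-d vector or q x d matrix.
#' @param block query rows per block.
#' @return Non-negative density value(s), one per query row.
#' @export
rvkde_density <- function(model, v, block = 1024L) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  v <- as.matrix(v)
  if (ncol(v) != model$d)
    stop(sprintf("query dimension %d does not match model dimension %d",
                 ncol(v), model$d), call. = FALSE)
  out <- numeric(nrow(v))
  for (start in seq(1L, nrow(v), by = block)) {
    idx <- start:min(start + block - 1L, nrow(v))
    out[idx] <- rvkde_density_block(model, v[idx, , drop = FALSE])
  }
  out
}

# Density of each training sample under its own model with the sample's own
# kernel excluded (leave-one-out).  Used by the screening stage: including
# the self-kernel would inflate every case's own-group density.
rvkde_density_loo <- function(model, block = 1024L) {
  n <- nrow(model$samples)
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- cross_dist2(model$samples[idx, , drop = FALSE], model$samples)
    d2[cbind(seq_along(idx), idx)] <- Inf
    coef <- (1 / (sqrt(2 * pi) * model$bandwidths))^model$d
    kernels <- exp(-sweep(d2, 2, 2 * model$bandwidths^2, `/`))
    out[idx] <- as.vector(kernels %*% coef) / (n - 1)
  }
  out
}

#' Serialize / restore an RVKDE model as structured text
#'
#' Plain-text checkpoint format: a key-value header (`k`, `beta`, `d`, `n`,
#' `sigma_floor`) followed by the bandwidth vector and the sample matrix,
#' all at full double precision.
#'
#' @param model an `rvkde` model.
#' @param path file path.
#' @return `read_rvkde()` returns the restored model.
#' @export
write_rvkde <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format\trvkde/1",
               sprintf("k\t%d", model$k),
               sprintf("beta\t%.17g", model$beta),
               sprintf("d\t%d", model$d),
               sprintf("n\t%d", nrow(model$samples)),
               sprintf("sigma_floor\t%.17g", model$sigma_floor),
               paste(sprintf("%.17g", model$bandwidths), collapse = "\t")),
             con)
  utils::write.table(format(model$samples, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_rvkde
#' @export
read_rvkde <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\t")
  stopifnot(hdr[[1]][2] == "rvkde/1")
  k <- as.integer(hdr[[2]][2]); beta <- as.numeric(hdr[[3]][2])
  d <- as.integer(hdr[[4]][2]); n <- as.integer(hdr[[5]][2])
  floor_val <- as.numeric(hdr[[6]][2])
  bw <- as.numeric(strsplit(lines[7], "\t")[[1]])
  samples <- matrix(as.numeric(unlist(strsplit(lines[8:(7 + n)], "\t"))),
                    nrow = n, ncol = d, byrow = TRUE)
  structure(list(samples = samples, bandwidths = bw, k = k, beta = beta,
                 d = d, sigma_floor = floor_val), class = "rvkde")
}

#' Grid-search (k, beta) by held-out log-likelihood
#'
#' Utility for users who want data-driven smoothing: simple v-fold
#' cross-validation over a (k, beta) grid, scoring mean held-out log
#' density.  Never applied automatically.
#'
#' @param samples n x d matrix.
#' @param k_grid,beta_grid candidate values.
#' @param folds number of folds.
#' @param rng_seed seed for the fold split.
#' @return Data frame of grid points with mean held-out log density, best
#'   first.
#' @export
rvkde_grid_search <- function(samples, k_grid = c(5, 10, 20),
                              beta_grid = c(0.5, 1, 2), folds = 5,
                              rng_seed = 1L) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  set.seed(rng_seed)
  fold <- sample(rep_len(seq_len(folds), n))
  grid <- expand.grid(k = k_grid, beta = beta_grid)
  grid$mean_loglik <- NA_real_
  for (g in seq_len(nrow(grid))) {
    ll <- numeric(folds)
    ok <- TRUE
    for (f in seq_len(folds)) {
      train <- samples[fold != f, , drop = FALSE]
      test <- samples[fold == f, , drop = FALSE]
      if (nrow(train) <= grid$k[g]) { ok <- FALSE; break }
      m <- fit_rvkde(train, k = grid$k[g], beta = grid$beta[g])
      dens <- rvkde_density(m, test)
      ll[f] <- mean(log(pmax(dens, .Machine$double.xmin)))
    }
    if (ok) grid$mean_loglik[g] <- mean(ll)
  }
  grid[order(-grid$mean_loglik), ]
}
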