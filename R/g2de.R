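# Compact mixture of generalized Gaussian components (G2DE).
#
# The density is a weight-normalized sum of K full-covariance Gaussian
# components,
#
#   f(v) = (1 / sum_i w_i) * sum_i (2*pi)^(-d/2) * GGC(w_i, mu_i, Sigma_i)
#   GGC(w, mu, Sigma) = w * |Sigma|^(-1/2) * exp(-1/2 (v-mu)' Sigma^{-1} (v-mu))
#
# with K kept small so the K(d+2)(d+1)/2 parameters stay interpretable:
# each component summarizes one cluster of samples through its weight,
# center and covariance.  Fitting is maximum-likelihood EM with seeded
# k-means++ initialization, multiple restarts and ridge-regularized
# covariances; components are ordered by descending weight so cluster 0 is
# always the majority cluster.

#' Value of a single generalized Gaussian component
#'
#' `w * |Sigma|^(-1/2) * exp(-(v-mu)' Sigma^{-1} (v-mu) / 2)` — note the
#' `(2*pi)^(d/2)` normalizer is applied in [g2de_density()], not here.
#'
#' @param w component weight (>= 0).
#' @param mu length-d center.
#' @param Sigma d x d symmetric positive-definite covariance.
#' @param v length-d evaluation point.
#' @return Non-negative scalar.
#' @export
g2de_component <- function(w, mu, Sigma, v) {
  Sigma <- as.matrix(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("covariance is not positive definite (smallest eigenvalue %g)",
                 min(ev)), call. = FALSE)
  ch <- chol(Sigma)
  z <- backsolve(ch, v - mu, transpose = TRUE)
  w * exp(-sum(z^2) / 2) / prod(diag(ch))
}

# log of (2*pi)^(-d/2) * |Sigma|^(-1/2) * exp(-maha/2) for all rows of x
log_gauss <- function(x, mu, Sigma) {
  d <- ncol(x)
  ch <- chol(Sigma)
  z <- backsolve(ch, t(sweep(x, 2, mu)), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

#' Mixture density of a G2DE model
#'
#' Weight-normalized sum of the components with the `(2*pi)^(-d/2)`
#' normalizer; integrates to 1 analytically for any valid model.
#'
#' @param model a `g2de` model.
#' @param v length-d vector or q x d matrix of evaluation points.
#' @return Non-negative density value(s).
#' @export
g2de_density <- function(model, v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  v <- as.matrix(v)
  if (ncol(v) != model$d)
    stop(sprintf("query dimension %d does not match model dimension %d",
                 ncol(v), model$d), call. = FALSE)
  w <- model$weights / sum(model$weights)
  dens <- numeric(nrow(v))
  for (i in seq_len(model$K))
    dens <- dens + w[i] * exp(log_gauss(v, model$means[i, ], model$covariances[[i]]))
  dens
}

#' Number of free parameters of a K-component model in d dimensions
#'
#' `K * (d + 2) * (d + 1) / 2`: per component one weight, d center
#' coordinates and d(d+1)/2 covariance entries.
#'
#' @param K number of components.
#' @param d dimension.
#' @return Integer parameter count.
#' @export
g2de_param_count <- function(K, d) {
  stopifnot(K >= 1, d >= 1)
  as.integer(K * (d + 2) * (d + 1) / 2)
}

# k-means++ center seeding: first center uniform, subsequent centers drawn
# with probability proportional to squared distance to the nearest chosen
# center
kmeanspp_centers <- function(data, K) {
  n <- nrow(data)
  centers <- matrix(NA_real_, K, ncol(data))
  centers[1, ] <- data[sample.int(n, 1), ]
  if (K > 1) {
    d2 <- rowSums(sweep(data, 2, centers[1, ])^2)
    for (j in 2:K) {
      if (sum(d2) <= 0) {
        pick <- sample.int(n, 1)
      } else {
        pick <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- data[pick, ]
      d2 <- pmin(d2, rowSums(sweep(data, 2, centers[j, ])^2))
    }
  }
  centers
}

regularize_cov <- function(S, lambda) {
  S + diag(lambda * sum(diag(S)) / nrow(S) + 1e-12, nrow(S))
}

em_once <- function(data, K, lambda, max_iter, tol, weight_floor) {
  n <- nrow(data); d <- ncol(data)
  centers <- kmeanspp_centers(data, K)
  assign0 <- max.col(-cross_dist2(data, centers))
  pi_k <- tabulate(assign0, K) / n
  pi_k <- pmax(pi_k, 1 / n)
  pi_k <- pi_k / sum(pi_k)
  mu <- centers
  Sig <- vector("list", K)
  S_all <- stats::cov(data) * (n - 1) / n
  for (j in seq_len(K)) {
    idx <- which(assign0 == j)
    Sig[[j]] <- if (length(idx) > d) {
      regularize_cov(stats::cov(data[idx, , drop = FALSE]) *
                       (length(idx) - 1) / length(idx), lambda)
    } else {
      regularize_cov(S_all, lambda)
    }
  }

  loglik_trace <- numeric(0)
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    logp <- matrix(NA_real_, n, K)
    for (j in seq_len(K))
      logp[, j] <- log(pi_k[j]) + log_gauss(data, mu[j, ], Sig[[j]])
    m <- apply(logp, 1, max)
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(logp - lse)

    nk <- colSums(resp)
    if (any(nk / n < weight_floor))
      return(list(ok = FALSE, reason = "component collapse"))
    pi_k <- nk / n
    for (j in seq_len(K)) {
      mu[j, ] <- colSums(resp[, j] * data) / nk[j]
      xc <- sweep(data, 2, mu[j, ])
      Sig[[j]] <- regularize_cov(crossprod(xc * sqrt(resp[, j])) / nk[j], lambda)
    }
    if (is.finite(prev_ll) && ll - prev_ll < tol * abs(ll)) break
    prev_ll <- ll
  }
  list(ok = TRUE, pi_k = pi_k, nk = nk, mu = mu, Sig = Sig,
       loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace, n_iter = length(loglik_trace))
}

#' Fit a G2DE mixture by maximum-likelihood EM
#'
#' Expectation-maximization with k-means++ initialization, `n_restarts`
#' independent seeded restarts (best final log-likelihood wins) and ridge
#' regularization `lambda * trace(S)/d` added to every covariance diagonal.
#' A restart whose smallest component share falls below `weight_floor` is
#' discarded as collapsed.  Components are sorted by descending weight, so
#' component 1 (cluster label 0) is always the majority cluster.
#'
#' @param data n x d numeric matrix; requires `n >= K * (d + 1)`.
#' @param K number of components (kept small for interpretability).
#' @param n_restarts independent EM restarts.
#' @param rng_seed seed controlling initialization; the fit is deterministic
#'   given `(data, K, n_restarts, rng_seed)`.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param lambda covariance ridge coefficient.
#' @param weight_floor minimum component share before a restart counts as
#'   collapsed.
#' @return Object of class `g2de`: `K`, `d`, `weights` (soft counts, i.e.
#'   unnormalized; shares are `weights/sum(weights)`), `means` (K x d),
#'   `covariances` (list of d x d), `loglik`, `loglik_trace`, `n_iter`.
#' @export
fit_g2de <- function(data, K = 2, n_restarts = 5, rng_seed = 1L,
                     max_iter = 500, tol = 1e-10, lambda = 1e-6,
                     weight_floor = 1e-8) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  n <- nrow(data); d <- ncol(data)
  if (n < K * (d + 1))
    stop(sprintf("need n >= K*(d+1) samples to fit %d components in %d dimensions (n = %d)",
                 K, d, n), call. = FALSE)

  best <- NULL
  failures <- character(0)
  for (r in seq_len(n_restarts)) {
    set.seed(rng_seed + r - 1L)
    fit <- em_once(data, K, lambda, max_iter, tol, weight_floor)
    if (!fit$ok) { failures <- c(failures, fit$reason); next }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("every EM restart failed (", paste(unique(failures), collapse = "; "),
         ")", call. = FALSE)

  ord <- order(best$nk, decreasing = TRUE)
  structure(list(
    K = K, d = d,
    weights = best$nk[ord],
    means = best$mu[ord, , drop = FALSE],
    covariances = best$Sig[ord],
    loglik = best$loglik,
    loglik_trace = best$loglik_trace,
    n_iter = best$n_iter
  ), class = "g2de")
}

# posterior responsibilities, n x K
g2de_responsibilities <- function(model, data) {
  data <- as.matrix(data)
  w <- model$weights / sum(model$weights)
  logp <- matrix(NA_real_, nrow(data), model$K)
  for (j in seq_len(model$K))
    logp[, j] <- log(w[j]) + log_gauss(data, model$means[j, ],
                                       model$covariances[[j]])
  m <- apply(logp, 1, max)
  exp(logp - (m + log(rowSums(exp(logp - m)))))
}

#' Assign observations to mixture components
#'
#' Each row goes to the component with maximal posterior responsibility;
#' exact ties break toward the lower component index.  Labels are 0-based
#' (cluster 0 = majority component) to match the reporting convention.
#'
#' @param model a fitted `g2de` model.
#' @param data n x d matrix.
#' @return Integer vector of cluster labels in `0:(K-1)`.
#' @export
assign_clusters <- function(model, data) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  if (ncol(data) != model$d)
    stop("data dimension does not match model", call. = FALSE)
  resp <- g2de_responsibilities(model, data)
  max.col(resp, ties.method = "first") - 1L
}

#' BIC over a range of component counts
#'
#' Helper for choosing K: fits each candidate and reports
#' `-2 loglik + p log(n)` with `p = K(d+2)(d+1)/2`.  Never applied
#' automatically — K is an analysis choice.
#'
#' @inheritParams fit_g2de
#' @param K_range candidate component counts.
#' @return Data frame with `K`, `loglik`, `bic`.
#' @export
g2de_bic <- function(data, K_range = 1:4, n_restarts = 3, rng_seed = 1L) {
  data <- as.matrix(data)
  out <- data.frame(K = K_range, loglik = NA_real_, bic = NA_real_)
  for (i in seq_along(K_range)) {
    fit <- fit_g2de(data, K = K_range[i], n_restarts = n_restarts,
                    rng_seed = rng_seed)
    out$loglik[i] <- fit$loglik
    out$bic[i] <- -2 * fit$loglik +
      g2de_param_count(K_range[i], ncol(data)) * log(nrow(data))
  }
  out
}

#' Serialize / restore a G2DE model as structured text
#'
#' @param model a `g2de` model.
#' @param path file path.
#' @return `read_g2de()` returns the restored model.
#' @export
write_g2de <- function(model, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = "\t")
  lines <- c("format\tg2de/1",
             sprintf("K\t%d", model$K),
             sprintf("d\t%d", model$d),
             sprintf("loglik\t%.17g", model$loglik),
             paste0("weights\t", num(model$weights)))
  for (j in seq_len(model$K)) {
    lines <- c(lines,
               paste0(sprintf("mean_%d\t", j), num(model$means[j, ])),
               paste0(sprintf("cov_%d\t", j), num(as.vector(t(model$covariances[[j]])))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_g2de
#' @export
read_g2de <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  stopifnot(lines[[1]][2] == "g2de/1")
  K <- as.integer(lines[[2]][2]); d <- as.integer(lines[[3]][2])
  loglik <- as.numeric(lines[[4]][2])
  weights <- as.numeric(lines[[5]][-1])
  means <- matrix(NA_real_, K, d)
  covs <- vector("list", K)
  for (j in seq_len(K)) {
    means[j, ] <- as.numeric(lines[[4 + 2 * j]][-1])
    covs[[j]] <- matrix(as.numeric(lines[[5 + 2 * j]][-1]), d, d, byrow = TRUE)
  }
  structure(list(K = K, d = d, weights = weights, means = means,
                 covariances = covs, loglik = loglik,
                 loglik_trace = loglik, n_iter = NA_integer_),
            class = "g2de")
}
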