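# Stage 2 preamble: normalization, factor-analysis adequacy checks, factor
# retention, orthogonal rotation, loading-threshold feature selection.
#
# The clustering stage needs a low-dimensional, interpretable feature
# subspace.  Following standard exploratory-factor-analysis practice:
# min-max normalize, check sampling adequacy (KMO > 0.5) and sphericity
# (Bartlett), extract principal components of the correlation matrix, keep
# eigenvalues strictly greater than 1, rotate orthogonally (varimax) and
# keep the original features with a rotated loading above the cutoff
# (default 0.4, absolute value).

#' Min-max normalization to [0, 1]
#'
#' Maps every non-constant column to `(x - min) / (max - min)`; constant
#' columns (undefined under the formula) map to 0.  The per-column min/max
#' are recorded so later data can be projected onto the same scale.
#'
#' @param x n x d numeric matrix.
#' @return List: `matrix` (normalized), `mins`, `maxs` (named per column).
#' @export
min_max_normalize <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  span <- maxs - mins
  out <- sweep(x, 2, mins)
  nz <- span > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, span[nz], `/`)
  out[, !nz] <- 0
  list(matrix = out, mins = mins, maxs = maxs)
}

#' Apply / invert a recorded min-max mapping
#'
#' @param x matrix to (de)normalize.
#' @param norm a [min_max_normalize()] record.
#' @return Matrix on the target scale.
#' @export
apply_min_max <- function(x, norm) {
  x <- as.matrix(x)
  span <- norm$maxs - norm$mins
  out <- sweep(x, 2, norm$mins)
  nz <- span > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, span[nz], `/`)
  out[, !nz] <- 0
  out
}

#' @rdname apply_min_max
#' @export
invert_min_max <- function(x, norm) {
  x <- as.matrix(x)
  span <- norm$maxs - norm$mins
  sweep(sweep(x, 2, span, `*`), 2, norm$mins, `+`)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: `sum(r_ij^2) / (sum(r_ij^2) + sum(p_ij^2))` over off-diagonal
#' pairs, where `p_ij` are the partial correlations obtained from the
#' inverse correlation matrix.  Values above 0.5 are conventionally deemed
#' adequate for factor analysis.
#'
#' @param x n x d data matrix, or a d x d correlation matrix (detected by
#'   symmetry with unit diagonal).
#' @return KMO value in [0, 1].
#' @export
kmo_statistic <- function(x) {
  R <- as_correlation(x)
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; regularize or drop collinear features",
         call. = FALSE))
  s <- diag(1 / sqrt(diag(Rinv)))
  P <- -s %*% Rinv %*% s     # partial correlations, off-diagonal
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(P[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests that the correlation matrix is the identity:
#' `statistic = -(n - 1 - (2d + 5)/6) * ln det(R)` on `d(d-1)/2` degrees of
#' freedom, with an upper-tail chi-square p-value.
#'
#' @param x n x d data matrix.
#' @param n sample size (only needed when `x` is already a correlation
#'   matrix).
#' @return List: `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(x, n = NULL) {
  R <- as_correlation(x)
  if (is.null(n)) {
    if (is_corr_matrix(x))
      stop("supply the sample size n when passing a correlation matrix",
           call. = FALSE)
    n <- nrow(x)
  }
  d <- ncol(R)
  detR <- det(R)
  if (detR <= 0)
    stop("correlation matrix is not positive definite", call. = FALSE)
  stat <- -(n - 1 - (2 * d + 5) / 6) * log(detR)
  df <- d * (d - 1) / 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

is_corr_matrix <- function(x) {
  is.matrix(x) && nrow(x) == ncol(x) &&
    isTRUE(all.equal(unname(diag(x)), rep(1, ncol(x)), tolerance = 1e-8)) &&
    isTRUE(all.equal(x, t(x), tolerance = 1e-8))
}

as_correlation <- function(x) {
  x <- as.matrix(x)
  if (is_corr_matrix(x)) return(x)
  stats::cor(x)
}

#' Retain factors with eigenvalue strictly greater than 1
#'
#' Principal-component extraction: eigendecomposition of the correlation
#' matrix, retention of components whose eigenvalue exceeds 1 (strictly —
#' an eigenvalue of exactly 1 carries no more variance than a single
#' standardized variable and is dropped), loadings = eigenvector *
#' sqrt(eigenvalue).
#'
#' @param correlation d x d correlation matrix.
#' @return List: `eigenvalues` (descending), `n_factors`, `loadings`
#'   (d x n_factors, possibly 0 columns).
#' @export
retain_factors <- function(correlation) {
  correlation <- as.matrix(correlation)
  e <- eigen(correlation, symmetric = TRUE)
  keep <- which(e$values > 1)
  loadings <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  rownames(loadings) <- rownames(correlation)
  list(eigenvalues = e$values, n_factors = length(keep), loadings = loadings)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax simple-structure criterion
#' (iterated pairwise rotations, convergence tolerance 1e-8).  A single
#' factor has no rotational freedom and is returned unchanged.
#'
#' @param loadings d x m loading matrix.
#' @param normalize Kaiser row-normalization before rotation.
#' @return List: `loadings` (rotated), `rotation` (m x m orthogonal matrix).
#' @export
varimax_rotate <- function(loadings, normalize = TRUE) {
  loadings <- as.matrix(loadings)
  m <- ncol(loadings)
  if (m <= 1)
    return(list(loadings = loadings, rotation = diag(1, m)))
  v <- stats::varimax(loadings, normalize = normalize, eps = 1e-8)
  rot <- unclass(v$loadings)
  attr(rot, "class") <- NULL
  list(loadings = rot, rotation = v$rotmat)
}

#' Select features by maximal absolute rotated loading
#'
#' Keeps the original features whose largest absolute loading across the
#' rotated factors strictly exceeds `cutoff`, in original column order.
#'
#' @param rotated_loadings d x m matrix with feature row names.
#' @param cutoff positive loading threshold (default 0.4).
#' @return Character vector of selected feature names (may be empty, with a
#'   warning).
#' @export
select_features <- function(rotated_loadings, cutoff = 0.4) {
  stopifnot(cutoff > 0)
  rotated_loadings <- as.matrix(rotated_loadings)
  if (ncol(rotated_loadings) == 0) {
    warning("no factors retained; no features selected")
    return(character(0))
  }
  maxload <- apply(abs(rotated_loadings), 1, max)
  sel <- rownames(rotated_loadings)[maxload > cutoff]
  if (length(sel) == 0) warning("no feature exceeds the loading cutoff")
  sel
}

#' Full factor-analysis feature-selection pass
#'
#' Correlation, adequacy checks (KMO, Bartlett — reported, never hard
#' gates), eigenvalue-above-one retention, varimax rotation, loading-cutoff
#' selection.  Zero-variance columns carry no correlation information; they
#' are excluded from the analysis (and can never be selected), and are
#' reported in `dropped`.
#'
#' @param x n x d data matrix with column names.
#' @param cutoff loading cutoff for [select_features()].
#' @param warn_adequacy emit warnings when KMO <= 0.5 or Bartlett p >= 0.05.
#' @return Object of class `factor_selection`: `correlation`,
#'   `eigenvalues`, `n_factors`, `loadings`, `rotated_loadings`,
#'   `rotation`, `selected_features`, `kmo`, `bartlett_stat`, `bartlett_df`,
#'   `bartlett_p`, `dropped`, `cutoff`.
#' @export
run_factor_selection <- function(x, cutoff = 0.4, warn_adequacy = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  const <- apply(x, 2, function(col) diff(range(col)) == 0)
  dropped <- colnames(x)[const]
  if (length(dropped) > 0)
    warning("zero-variance columns excluded from factor analysis: ",
            paste(dropped, collapse = ", "))
  xa <- x[, !const, drop = FALSE]

  # perfectly collinear pairs (e.g. a drug's duration and dosage when only
  # one subject utilizes it) make the correlation matrix singular; keep the
  # first column of any such pair
  R <- stats::cor(xa)
  repeat {
    dup <- which(abs(R) > 1 - 1e-10 & upper.tri(R), arr.ind = TRUE)
    if (nrow(dup) == 0) break
    drop_col <- colnames(R)[max(dup[, 2])]
    warning("collinear column excluded from factor analysis: ", drop_col)
    dropped <- c(dropped, drop_col)
    xa <- xa[, colnames(xa) != drop_col, drop = FALSE]
    R <- stats::cor(xa)
  }
  kmo <- kmo_statistic(R)
  bart <- bartlett_sphericity(R, n = nrow(xa))
  if (warn_adequacy) {
    if (kmo <= 0.5)
      warning(sprintf("KMO %.3f is at or below the adequacy threshold 0.5", kmo))
    if (bart$p_value >= 0.05)
      warning(sprintf("Bartlett sphericity p = %.3g is not significant",
                      bart$p_value))
  }

  ret <- retain_factors(R)
  rot <- varimax_rotate(ret$loadings)
  selected <- if (ret$n_factors > 0) select_features(rot$loadings, cutoff)
              else {
                warning("no factors retained (no eigenvalue exceeds 1)")
                character(0)
              }
  # original column order
  selected <- colnames(x)[colnames(x) %in% selected]

  structure(list(
    correlation = R, eigenvalues = ret$eigenvalues,
    n_factors = ret$n_factors, loadings = ret$loadings,
    rotated_loadings = rot$loadings, rotation = rot$rotation,
    selected_features = selected, kmo = kmo,
    bartlett_stat = bart$statistic, bartlett_df = bart$df,
    bartlett_p = bart$p_value, dropped = dropped, cutoff = cutoff
  ), class = "factor_selection")
}
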