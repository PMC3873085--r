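# Synthetic validation fixtures with known ground truth.
#
# Unlike generate_cohort(), which emulates a realistic claims cohort, these
# two generators produce idealized Gaussian data with planted structure
# whose recovery the screening and feature-selection stages can be scored
# against exactly.

#' Two-population screening fixture
#'
#' Cases are a mixture: `1 - distinct_fraction` share the control
#' distribution (standard Gaussian) and `distinct_fraction` come from a
#' shifted Gaussian absent among the controls.  The generating labels are
#' the oracle for screening recall/precision.
#'
#' @param n_cases,n_controls sample sizes.
#' @param distinct_fraction share of cases from the shifted population.
#' @param shift mean of the distinct population (applied to every
#'   coordinate).
#' @param d dimension.
#' @param rng_seed seed.
#' @return List: `cases` (matrix), `controls` (matrix), `is_distinct`
#'   (logical oracle labels for the cases).
#' @export
simulate_screening_fixture <- function(n_cases = 1000, n_controls = 2000,
                                       distinct_fraction = 0.3, shift = 4,
                                       d = 2, rng_seed = 1L) {
  set.seed(rng_seed)
  n_distinct <- round(distinct_fraction * n_cases)
  bulk <- matrix(stats::rnorm((n_cases - n_distinct) * d), ncol = d)
  distinct <- matrix(stats::rnorm(n_distinct * d, mean = shift), ncol = d)
  cases <- rbind(bulk, distinct)
  controls <- matrix(stats::rnorm(n_controls * d), ncol = d)
  rownames(cases) <- sprintf("case_%04d", seq_len(n_cases))
  list(cases = cases, controls = controls,
       is_distinct = c(rep(FALSE, n_cases - n_distinct),
                       rep(TRUE, n_distinct)))
}

#' Correlated exposure-feature fixture with planted dosage factors
#'
#' Draws a 10-column feature matrix (the usual duration/dosage pairs) from
#' a two-factor Gaussian latent model: the dosage columns load one of two
#' drug-group factors strongly, the duration columns load both factors
#' weakly.  At the population level, eigenvalue-above-one retention
#' followed by varimax rotation and the 0.4 loading cutoff selects exactly
#' the five dosage columns; the duration loadings (about 0.33) and the
#' residual duration eigenvalues (about 0.93) both sit several sampling
#' standard errors away from their respective decision boundaries at the
#' default sample size.
#'
#' @param n sample size (default 8000).
#' @param rng_seed seed.
#' @param dosage_loading,dosage_loading2 latent loadings of the two dosage
#'   groups (amitriptyline/flunarizine/propranolol and
#'   topiramate/valproic acid).
#' @param duration_loading latent loading of every duration column on each
#'   of the two factors.
#' @return Numeric matrix with the columns of [exposure_feature_names()].
#' @export
simulate_factor_fixture <- function(n = 8000, rng_seed = 1L,
                                    dosage_loading = 0.78,
                                    dosage_loading2 = 0.80,
                                    duration_loading = 0.19) {
  set.seed(rng_seed)
  L <- matrix(0, 10, 2)
  dos <- seq(2, 10, 2); dur <- seq(1, 9, 2)
  L[dos[1:3], 1] <- dosage_loading
  L[dos[4:5], 2] <- dosage_loading2
  L[dur, 1] <- duration_loading
  L[dur, 2] <- duration_loading
  f <- matrix(stats::rnorm(n * 2), n, 2)
  e <- matrix(stats::rnorm(n * 10), n, 10)
  x <- f %*% t(L) + sweep(e, 2, sqrt(1 - rowSums(L^2)), `*`)
  colnames(x) <- exposure_feature_names()
  x
}
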