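# Stage 1: likelihood-ratio screening of cases.
#
# One RVKDE density is fitted on the cases (f) and another on the controls
# (f').  A case s_i is labeled "of interest" when f(s_i) / f'(s_i) exceeds
# a threshold (strict inequality): it sits in a region of exposure space
# where cases concentrate relative to controls, i.e. it carries features
# distinctive of the case population.

#' Case/control density likelihood ratio at a point
#'
#' `rvkde_density(case_model, v) / rvkde_density(control_model, v)`.  When
#' the control density underflows below `floor`, the ratio is reported as
#' the large sentinel `1/floor` and the event is signalled as a condition
#' message (the point lies so far outside the control population that the
#' ratio is effectively infinite).
#'
#' @param case_model,control_model fitted [fit_rvkde()] models of equal
#'   dimension.
#' @param v length-d vector or q x d matrix.
#' @param floor numeric floor for the control density.
#' @return Positive ratio value(s).
#' @export
likelihood_ratio <- function(case_model, control_model, v, floor = 1e-300) {
  if (case_model$d != control_model$d)
    stop("case and control models have different dimensions", call. = FALSE)
  num <- rvkde_density(case_model, v)
  den <- rvkde_density(control_model, v)
  low <- den < floor
  if (any(low)) {
    message(sprintf(
      "likelihood_ratio: control density below %g at %d point(s); sentinel ratio used",
      floor, sum(low)))
    den[low] <- floor
  }
  num / den
}

#' Screen cases of interest by density likelihood ratio
#'
#' Fits one RVKDE model on the case rows and one on the control rows (each
#' group on its own data only), evaluates every case's ratio
#' f_case / f_control, and selects cases with ratio strictly greater than
#' `threshold`.  By default a case's own kernel is excluded when its
#' case-density is evaluated (`exclude_self = TRUE`): including it would
#' systematically inflate every ratio, since each case is by construction a
#' training sample of the case model but not of the control model.
#'
#' @param cases,controls feature matrices with equal column count (rows:
#'   subjects; typically min-max normalized exposure features).
#' @param k,beta RVKDE hyper-parameters, shared by both fits.
#' @param threshold selection threshold on the ratio (strict `>`).
#' @param exclude_self drop the self-kernel when evaluating a case under
#'   the case model.
#' @param floor control-density floor forwarded to [likelihood_ratio()].
#' @return Object of class `screening_result`: `ratios` (one per case, in
#'   row order), `threshold`, `selected` (logical), `selected_ids` (row
#'   names of the selected cases, when present), `case_model`,
#'   `control_model`.
#' @export
select_of_interest <- function(cases, controls, k = 10, beta = 1,
                               threshold = 1, exclude_self = TRUE,
                               floor = 1e-300) {
  cases <- as.matrix(cases); controls <- as.matrix(controls)
  if (ncol(cases) != ncol(controls))
    stop("case and control feature matrices must share columns", call. = FALSE)
  case_model <- fit_rvkde(cases, k = k, beta = beta)
  control_model <- fit_rvkde(controls, k = k, beta = beta)
  # harmonize the degenerate-bandwidth floor across the two fits: duplicate
  # feature vectors (e.g. the all-zero exposure profile) appear in both
  # groups, and their density spikes must be commensurable for the ratio to
  # reflect the groups' relative mass at that point
  shared_floor <- max(case_model$sigma_floor, control_model$sigma_floor)
  case_model$bandwidths <- pmax(case_model$bandwidths, shared_floor)
  control_model$bandwidths <- pmax(control_model$bandwidths, shared_floor)
  case_model$sigma_floor <- control_model$sigma_floor <- shared_floor

  num <- if (exclude_self) rvkde_density_loo(case_model)
         else rvkde_density(case_model, cases)
  den <- rvkde_density(control_model, cases)
  low <- den < floor
  if (any(low)) {
    message(sprintf(
      "select_of_interest: control density below %g for %d case(s); sentinel ratio used",
      floor, sum(low)))
    den[low] <- floor
  }
  ratios <- num / den
  selected <- ratios > threshold

  structure(list(
    ratios = ratios, threshold = threshold, selected = selected,
    selected_ids = rownames(cases)[selected],
    case_model = case_model, control_model = control_model
  ), class = "screening_result")
}

#' Threshold achieving a target selected fraction
#'
#' For analyses that want a given share of cases flagged (rather than a
#' fixed ratio cutoff), returns the threshold under which strictly greater
#' ratios make up approximately `fraction` of the cases.
#'
#' @param ratios vector of case likelihood ratios.
#' @param fraction target selected fraction in (0, 1).
#' @return Threshold value.
#' @export
threshold_for_fraction <- function(ratios, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  as.numeric(stats::quantile(ratios, probs = 1 - fraction, type = 1))
}
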