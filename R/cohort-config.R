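#' Exposure distribution for one subpopulation
#'
#' Per-drug utilization probability and log-normal dosage/duration
#' parameters, conditional on utilization.  Dosage and duration are gated by
#' a single Bernoulli draw per (subject, drug): a subject either used the
#' drug (positive duration and dosage) or did not (both zero), so the
#' invariant `dosage_mg == 0 iff duration_days == 0` holds by construction.
#' Log-normals are parameterized by the target arithmetic mean and a log-sd,
#' since claims exposure distributions are strongly right-skewed (SDs exceed
#' means).
#'
#' @param p_use length-5 utilization probabilities, drug order of
#'   [migraine_drugs()].
#' @param dose_mean length-5 target mean cumulative dosage (mg) among users.
#' @param dur_mean length-5 target mean treatment duration (days) among users.
#' @param dose_sdlog,dur_sdlog log-scale standard deviations (scalar or
#'   length 5).
#' @return Data frame, one row per drug.
#' @export
exposure_profile <- function(p_use, dose_mean, dur_mean,
                             dose_sdlog = 1.3, dur_sdlog = 1.1) {
  drugs <- migraine_drugs()
  stopifnot(length(p_use) == 5, length(dose_mean) == 5, length(dur_mean) == 5)
  data.frame(
    drug = drugs,
    p_use = as.numeric(p_use),
    dose_meanlog = log(dose_mean) - rep_len(dose_sdlog, 5)^2 / 2,
    dose_sdlog = rep_len(dose_sdlog, 5),
    dur_meanlog = log(dur_mean) - rep_len(dur_sdlog, 5)^2 / 2,
    dur_sdlog = rep_len(dur_sdlog, 5),
    stringsAsFactors = FALSE
  )
}

default_case_clusters <- function() {
  list(
    # majority of cases: modest preventive-drug exposure
    bulk = exposure_profile(
      p_use     = c(0.011, 0.131, 0.342, 0.022, 0.006),
      dose_mean = c(35, 270, 1700, 4000, 11000),
      dur_mean  = c(4, 36, 69, 67, 31)
    ),
    # planted high-exposure subcluster: heavier utilization, much larger
    # cumulative dosages and longer durations for every drug
    high_exposure = exposure_profile(
      p_use     = c(0.40, 0.35, 0.76, 0.10, 0.067),
      dose_mean = c(1520, 2050, 15300, 44300, 112000),
      dur_mean  = c(58, 256, 438, 236, 181)
    )
  )
}

default_control_exposure <- function() {
  exposure_profile(
    p_use     = c(0.0035, 0.0249, 0.1034, 0.0010, 0.0014),
    dose_mean = c(2390, 300, 2750, 42100, 93800),
    dur_mean  = c(74, 35, 109, 283, 140)
  )
}

default_outcome_spec <- function() {
  data.frame(
    outcome   = c("depression", "anxiety_state", "bipolar_disorder",
                  "hypertension", "diabetes_mellitus", "epilepsy"),
    base_rate = c(0.050, 0.040, 0.010, 0.100, 0.060, 0.008),
    or_case   = c(3.2, 3.14, 2.11, 1.6, 1.16, 2.74),
    or_high_cluster = c(2.57, 2.68, 5.12, 2.4, 2.1, 3.55),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic matched cohort
#'
#' Describes a matched case-control cohort: how many cases, the matching
#' ratio, demographic composition, the mixture of case exposure
#' subpopulations (including a planted high-exposure subcluster), control
#' exposure, and Bernoulli outcome flags with planted case-vs-control odds
#' ratios.  Defaults emulate a national-claims migraine cohort: 27.5% male,
#' age bands 69.9/19.2/10.9%, index dates over 2004-2008, five preventive
#' drugs with rare-to-moderate utilization, and a small (7%) high-exposure
#' case subcluster.
#'
#' @param n_cases number of cases.
#' @param match_ratio matched controls per case (default 5).
#' @param p_male probability a case is male.
#' @param age_probs named probabilities of the three age bands
#'   (`le50`, `b51_64`, `ge65`), summing to 1.
#' @param index_window two dates bounding the uniform index-date draw.
#' @param cluster_fractions named proportions of the case exposure
#'   subpopulations; must sum to 1.
#' @param case_clusters named list (same names) of [exposure_profile()]
#'   data frames.
#' @param control_exposure [exposure_profile()] data frame for controls.
#' @param outcomes data frame with columns `outcome`, `base_rate` (control
#'   probability), `or_case` (planted case-vs-control odds ratio) and
#'   optionally `or_high_cluster` (extra odds multiplier for members of the
#'   `high_exposure` cluster).
#' @param followup_rate_case probability a case carries the follow-up flag
#'   (controls never do, by cohort construction).
#' @param rng_seed integer seed; the generated cohort is a pure function of
#'   the configuration including this seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 2000,
                          match_ratio = 5,
                          p_male = 0.275,
                          age_probs = c(le50 = 0.699, b51_64 = 0.192, ge65 = 0.109),
                          index_window = as.Date(c("2004-01-01", "2008-12-31")),
                          cluster_fractions = c(bulk = 0.93, high_exposure = 0.07),
                          case_clusters = default_case_clusters(),
                          control_exposure = default_control_exposure(),
                          outcomes = default_outcome_spec(),
                          followup_rate_case = 0.189,
                          rng_seed = 1L) {
  cfg <- structure(list(
    n_cases = n_cases, match_ratio = match_ratio, p_male = p_male,
    age_probs = age_probs, index_window = as.Date(index_window),
    cluster_fractions = cluster_fractions, case_clusters = case_clusters,
    control_exposure = control_exposure, outcomes = outcomes,
    followup_rate_case = followup_rate_case, rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort configuration: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_cases) || length(cfg$n_cases) != 1 ||
      cfg$n_cases < 1 || cfg$n_cases != round(cfg$n_cases))
    fail("n_cases", "must be a positive integer")
  if (!is.numeric(cfg$match_ratio) || cfg$match_ratio < 1 ||
      cfg$match_ratio != round(cfg$match_ratio))
    fail("match_ratio", "must be a positive integer")
  if (cfg$p_male < 0 || cfg$p_male > 1) fail("p_male", "must lie in [0, 1]")
  if (!setequal(names(cfg$age_probs), c("le50", "b51_64", "ge65")))
    fail("age_probs", "must be named le50, b51_64, ge65")
  if (any(cfg$age_probs < 0) || abs(sum(cfg$age_probs) - 1) > 1e-12)
    fail("age_probs", "must be non-negative and sum to 1")
  if (abs(sum(cfg$cluster_fractions) - 1) > 1e-12)
    fail("cluster_fractions", "must sum to 1")
  if (any(cfg$cluster_fractions < 0))
    fail("cluster_fractions", "must be non-negative")
  if (!setequal(names(cfg$cluster_fractions), names(cfg$case_clusters)))
    fail("case_clusters", "names must match cluster_fractions")
  for (nm in names(cfg$case_clusters)) {
    pu <- cfg$case_clusters[[nm]]$p_use
    if (any(pu < 0 | pu > 1))
      fail(sprintf("case_clusters$%s$p_use", nm), "must lie in [0, 1]")
  }
  if (any(cfg$control_exposure$p_use < 0 | cfg$control_exposure$p_use > 1))
    fail("control_exposure$p_use", "must lie in [0, 1]")
  oc <- cfg$outcomes
  if (any(oc$base_rate <= 0 | oc$base_rate >= 1))
    fail("outcomes$base_rate", "must lie in (0, 1)")
  if (any(oc$or_case <= 0)) fail("outcomes$or_case", "must be positive")
  if (!is.null(oc$or_high_cluster) && any(oc$or_high_cluster <= 0))
    fail("outcomes$or_high_cluster", "must be positive")
  if (cfg$followup_rate_case < 0 || cfg$followup_rate_case > 1)
    fail("followup_rate_case", "must lie in [0, 1]")
  if (length(cfg$rng_seed) != 1 || is.na(cfg$rng_seed))
    fail("rng_seed", "must be a single integer")
  invisible(cfg)
}
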