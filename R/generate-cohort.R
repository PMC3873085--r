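# Synthetic matched case-control cohort generation.
#
# The generator emulates the structure the two-stage analysis assumes:
# 1:ratio age/sex-matched controls sharing the case's index date, a
# 10-element drug-exposure feature vector per subject, a planted
# high-exposure case subcluster, and binary outcome flags realizing planted
# case-vs-control odds ratios in expectation.

draw_exposure <- function(n, profile) {
  out <- matrix(0, nrow = n, ncol = 10,
                dimnames = list(NULL, exposure_feature_names()))
  for (j in seq_len(5)) {
    row <- profile[j, ]
    use <- stats::runif(n) < row$p_use
    n_use <- sum(use)
    if (n_use > 0) {
      dur <- pmax(1, round(stats::rlnorm(n_use, row$dur_meanlog, row$dur_sdlog)))
      dose <- stats::rlnorm(n_use, row$dose_meanlog, row$dose_sdlog)
      out[use, 2L * j - 1L] <- dur
      out[use, 2L * j] <- dose
    }
  }
  out
}

draw_outcomes <- function(n, outcomes, odds_multiplier) {
  flags <- matrix(0L, nrow = n, ncol = nrow(outcomes),
                  dimnames = list(NULL, paste0("outcome_", outcomes$outcome)))
  for (j in seq_len(nrow(outcomes))) {
    base_odds <- outcomes$base_rate[j] / (1 - outcomes$base_rate[j])
    odds <- base_odds * odds_multiplier[, j]
    p <- odds / (1 + odds)
    flags[, j] <- as.integer(stats::runif(n) < p)
  }
  flags
}

#' Generate a matched case-control cohort
#'
#' Draws `n_cases` cases from the configured mixture of exposure
#' subpopulations, a control pool from the control exposure distribution,
#' matches `match_ratio` controls per case within (sex, age band) strata via
#' [match_controls()], and plants Bernoulli outcome flags whose
#' group-conditional odds realize the configured odds ratios in expectation.
#' Fully reproducible: the output is a pure function of `config` (including
#' `rng_seed`).
#'
#' @param config a [cohort_config()].
#' @return Subject table: a data frame with one row per subject and columns
#'   `subject_id`, `group` ("case"/"control"), `sex`, `age_band`,
#'   `match_set_id`, `index_date`, `followup_flag`, `true_cluster` (the
#'   generating exposure subpopulation — synthetic provenance, `NA` for
#'   controls), the ten exposure columns of [exposure_feature_names()], and
#'   one 0/1 `outcome_*` column per configured outcome.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$rng_seed)
  n <- as.integer(config$n_cases)
  ratio <- as.integer(config$match_ratio)
  drugs <- migraine_drugs()

  # --- cases ---------------------------------------------------------------
  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  age_band <- sample(names(config$age_probs), n, replace = TRUE,
                     prob = config$age_probs)
  window_days <- as.integer(diff(config$index_window))
  index_date <- config$index_window[1] +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L
  cluster <- sample(names(config$cluster_fractions), n, replace = TRUE,
                    prob = config$cluster_fractions)

  expo <- matrix(0, nrow = n, ncol = 10,
                 dimnames = list(NULL, exposure_feature_names()))
  for (nm in names(config$case_clusters)) {
    idx <- which(cluster == nm)
    if (length(idx) > 0)
      expo[idx, ] <- draw_exposure(length(idx), config$case_clusters[[nm]])
  }

  case_id <- sprintf("case_%06d", seq_len(n))
  cases <- data.frame(
    subject_id = case_id, group = "case", sex = sex, age_band = age_band,
    match_set_id = case_id, index_date = index_date,
    followup_flag = as.integer(stats::runif(n) < config$followup_rate_case),
    true_cluster = cluster, stringsAsFactors = FALSE
  )
  cases <- cbind(cases, as.data.frame(expo))

  # --- control pool: ratio eligible controls per case stratum --------------
  strata <- table(paste(sex, age_band, sep = "|"))
  pool_n <- ratio * n
  pool_sex <- character(pool_n); pool_age <- character(pool_n)
  pos <- 1L
  for (s in names(strata)) {
    m <- ratio * strata[[s]]
    parts <- strsplit(s, "|", fixed = TRUE)[[1]]
    pool_sex[pos:(pos + m - 1L)] <- parts[1]
    pool_age[pos:(pos + m - 1L)] <- parts[2]
    pos <- pos + m
  }
  pool <- data.frame(
    subject_id = sprintf("ctrl_%07d", seq_len(pool_n)), group = "control",
    sex = pool_sex, age_band = pool_age, match_set_id = NA_character_,
    index_date = config$index_window[1], followup_flag = 0L,
    true_cluster = NA_character_, stringsAsFactors = FALSE
  )
  pool <- cbind(pool, as.data.frame(draw_exposure(pool_n, config$control_exposure)))

  controls <- match_controls(cases, pool, ratio)

  # --- outcomes ------------------------------------------------------------
  # Planted case-vs-control ORs are exact in expectation at the margin:
  # when the high-exposure cluster carries an extra odds multiplier, the
  # bulk multiplier is solved so the mixture-averaged case probability
  # still realizes or_case against the control base rate.
  oc <- config$outcomes
  hi <- cluster == "high_exposure"
  f_hi <- mean(hi)
  mult_case <- matrix(NA_real_, nrow = n, ncol = nrow(oc))
  for (j in seq_len(nrow(oc))) {
    m_hi <- if (is.null(oc$or_high_cluster)) 1 else oc$or_high_cluster[j]
    b <- oc$base_rate[j] / (1 - oc$base_rate[j])
    target_p <- oc$or_case[j] * b / (1 + oc$or_case[j] * b)
    if (f_hi > 0 && m_hi != 1) {
      sig <- function(o) o / (1 + o)
      x <- stats::uniroot(function(x)
        (1 - f_hi) * sig(x * b) + f_hi * sig(x * m_hi * b) - target_p,
        lower = oc$or_case[j] / max(m_hi, 1) / 100,
        upper = oc$or_case[j] * 100, tol = 1e-12)$root
    } else {
      x <- oc$or_case[j]
    }
    mult_case[, j] <- ifelse(hi, x * m_hi, x)
  }
  cases <- cbind(cases, as.data.frame(draw_outcomes(n, oc, mult_case)))
  mult_ctrl <- matrix(1, nrow = nrow(controls), ncol = nrow(oc))
  controls <- cbind(controls, as.data.frame(draw_outcomes(nrow(controls), oc, mult_ctrl)))

  out <- rbind(cases, controls)
  rownames(out) <- NULL
  out
}

#' Match controls to cases within (sex, age band) strata
#'
#' Samples, without replacement, `ratio` controls per case from the pool
#' members sharing the case's sex and age band.  Selected controls inherit
#' the case's `match_set_id` and `index_date`, mirroring the matched design
#' in which the index date of the case is assigned to its controls.
#'
#' @param cases,pool subject tables (controls in `pool` need not be matched
#'   yet; their `match_set_id`/`index_date` are overwritten).
#' @param ratio controls per case.
#' @param rng_seed optional seed; if `NULL` the current RNG state is used.
#' @return Subject table of the selected controls (`ratio` rows per case, in
#'   case order).
#' @export
match_controls <- function(cases, pool, ratio, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ratio <- as.integer(ratio)
  case_stratum <- paste(cases$sex, cases$age_band, sep = "|")
  pool_stratum <- paste(pool$sex, pool$age_band, sep = "|")

  need <- table(case_stratum) * ratio
  have <- table(pool_stratum)[names(need)]
  have[is.na(have)] <- 0L
  short <- names(need)[have < need]
  if (length(short) > 0) {
    stop(sprintf(
      "control pool exhausted in stratum (sex|age_band): %s (need %s, have %s)",
      paste(short, collapse = ", "),
      paste(need[short], collapse = ", "),
      paste(have[short], collapse = ", ")), call. = FALSE)
  }

  # sampling without replacement = one random permutation per stratum,
  # consumed in consecutive blocks of `ratio` (cases in input order)
  avail <- split(seq_len(nrow(pool)), pool_stratum)
  avail <- lapply(avail, function(ix) ix[sample.int(length(ix))])
  cursor <- stats::setNames(rep(1L, length(avail)), names(avail))
  picked <- integer(ratio * nrow(cases))
  set_id <- character(ratio * nrow(cases))
  idx_date <- rep(cases$index_date[1], ratio * nrow(cases))
  for (i in seq_len(nrow(cases))) {
    s <- case_stratum[i]
    take <- avail[[s]][cursor[[s]]:(cursor[[s]] + ratio - 1L)]
    cursor[[s]] <- cursor[[s]] + ratio
    slot <- ((i - 1L) * ratio + 1L):(i * ratio)
    picked[slot] <- take
    set_id[slot] <- cases$match_set_id[i]
    idx_date[slot] <- cases$index_date[i]
  }
  out <- pool[picked, , drop = FALSE]
  out$match_set_id <- set_id
  out$index_date <- idx_date
  rownames(out) <- NULL
  out
}

#' Extract the 10-column exposure feature matrix from a subject table
#'
#' @param subjects subject table (any row subset).
#' @return Numeric matrix, `nrow(subjects)` x 10, columns in the fixed
#'   drug-by-(duration, dosage) order; row order preserves input order and
#'   row names carry `subject_id`.
#' @export
subjects_to_features <- function(subjects) {
  if (nrow(subjects) == 0) stop("subject table is empty", call. = FALSE)
  cols <- exposure_feature_names()
  missing <- setdiff(cols, names(subjects))
  if (length(missing) > 0)
    stop("subject table lacks exposure columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(subjects[, cols])
  rownames(m) <- subjects$subject_id
  m
}

#' Write / read the subject table as delimited text
#'
#' Tab-separated, one header row, ISO-8601 dates, 0/1 booleans — the common
#' interchange format every analysis stage reads and writes.
#'
#' @param subjects subject table.
#' @param path file path.
#' @return `read_subject_table()` returns the subject table with
#'   `index_date` restored to `Date`.
#' @export
write_subject_table <- function(subjects, path) {
  out <- subjects
  out$index_date <- format(out$index_date, "%Y-%m-%d")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$index_date <- as.Date(x$index_date)
  x
}
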