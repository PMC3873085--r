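# Between-group statistics: 2x2 odds ratios with Woolf 95% CIs, chi-square
# and t tests, percentages, DDD conversion, and demographics-table assembly
# for any two-group partition of a cohort (case vs control, of-interest vs
# remaining, cluster 1 vs cluster 0).

#' 2x2 odds ratio with 95% confidence interval
#'
#' Cell layout: `a` exposed cases, `b` unexposed cases, `c` exposed
#' controls, `d` unexposed controls.  OR = (a*d)/(b*c); the CI is Woolf's
#' log-normal interval `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' When any cell is zero the Haldane-Anscombe +0.5 correction is applied to
#' all cells (flagged in the result).  The p-value is the uncorrected
#' Pearson chi-square test of the original table.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `odds_ratio_result`: `a`,`b`,`c`,`d`,
#'   `or_point`, `ci_low`, `ci_high`, `p_value`, `correction_applied`.
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("a margin of the 2x2 table is zero; odds ratio undefined",
         call. = FALSE)
  correction <- any(counts == 0)
  cc <- if (correction) counts + 0.5 else counts
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- chi_square_2x2(a, b, c, d)$p_value
  structure(list(
    a = a, b = b, c = c, d = d,
    or_point = unname(or),
    ci_low = unname(exp(log(or) - z * se)),
    ci_high = unname(exp(log(or) + z * se)),
    p_value = p, correction_applied = correction
  ), class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), p = %.3g%s\n",
              x$or_point, x$ci_low, x$ci_high, x$p_value,
              if (x$correction_applied) " [+0.5 correction]" else ""))
  invisible(x)
}

#' Pearson chi-square test of a 2x2 table
#'
#' Uncorrected by default (`n (ad - bc)^2` over the margin product, df = 1);
#' set `correct = TRUE` for the Yates continuity correction.
#'
#' @param a,b,c,d cell counts.
#' @param correct apply the continuity correction.
#' @return List: `statistic`, `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("a margin of the 2x2 table is zero", call. = FALSE)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Two-sample t test
#'
#' Two-tailed; Welch (unequal variances) by default, pooled optional.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param pooled assume equal variances.
#' @return List: `statistic`, `p_value`, `df`.
#' @export
two_sample_t <- function(x, y, pooled = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least two observations", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("both groups are degenerate (zero variance)", call. = FALSE)
  res <- stats::t.test(x, y, var.equal = pooled)
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       df = unname(res$parameter))
}

#' Convert a milligram dosage to defined daily doses
#'
#' `dosage_mg / mg_per_ddd`; with `duration_days` supplied, the average
#' daily exposure `dosage_mg / mg_per_ddd / duration_days` instead.
#'
#' @param dosage_mg cumulative dosage in milligrams.
#' @param drug drug name, present in `ddd_table`.
#' @param ddd_table data frame with `drug` and `mg_per_ddd` columns
#'   (default [default_ddd_table()]).
#' @param duration_days optional treatment days for the per-day average.
#' @return DDD value(s).
#' @export
ddd_convert <- function(dosage_mg, drug, ddd_table = default_ddd_table(),
                        duration_days = NULL) {
  row <- match(drug, ddd_table$drug)
  if (any(is.na(row)))
    stop("drug not present in DDD table: ",
         paste(drug[is.na(row)], collapse = ", "), call. = FALSE)
  const <- ddd_table$mg_per_ddd[row]
  if (any(const <= 0)) stop("mg_per_ddd must be positive", call. = FALSE)
  out <- dosage_mg / const
  if (!is.null(duration_days)) out <- out / duration_days
  out
}

#' Percentage of a count within a total
#'
#' @param count,total non-negative integers, `count <= total`, `total > 0`.
#' @return `100 * count / total` (full precision; round only for display).
#' @export
proportion <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(count < 0) || any(count > total))
    stop("count must lie in [0, total]", call. = FALSE)
  100 * count / total
}

#' Round half away from zero (display convention)
#'
#' Published cohort tables round 27.45 to 27.5; base `round()` rounds half
#' to even.  Display-only helper.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

demog_cat_row <- function(variable, flag, grp, levels) {
  n1 <- sum(grp == levels[1]); n2 <- sum(grp == levels[2])
  c1 <- sum(flag[grp == levels[1]]); c2 <- sum(flag[grp == levels[2]])
  p <- tryCatch(
    chi_square_2x2(c1, n1 - c1, c2, n2 - c2)$p_value,
    error = function(e) NA_real_)
  data.frame(variable = variable, type = "categorical",
             group1_n = c1, group1_stat = proportion(c1, n1),
             group2_n = c2, group2_stat = proportion(c2, n2),
             group1_sd = NA_real_, group2_sd = NA_real_,
             test = "chi-square", p_value = p, stringsAsFactors = FALSE)
}

demog_cont_row <- function(variable, values, grp, levels) {
  x <- values[[1]]; y <- values[[2]]
  res <- tryCatch(two_sample_t(x, y),
                  error = function(e) list(p_value = NA_real_))
  data.frame(variable = variable, type = "continuous",
             group1_n = length(x), group1_stat = mean(x),
             group2_n = length(y), group2_stat = mean(y),
             group1_sd = stats::sd(x), group2_sd = stats::sd(y),
             test = "t", p_value = res$p_value, stringsAsFactors = FALSE)
}

#' Demographics comparison table for a two-group partition
#'
#' Builds the standard cohort comparison table: sex, follow-up flag, age
#' bands, and per drug the utilization count/percentage plus — among
#' utilizers only, following the convention that exposure statistics
#' describe the exposed — mean (SD) dosage (mg), duration (days),
#' cumulative DDD and average daily DDD.  Categorical rows use the
#' chi-square test, continuous rows the Welch t test.
#'
#' @param subjects subject table.
#' @param partition either the name of a column in `subjects` or a vector
#'   with one entry per subject; must have exactly two distinct values.
#' @param group_levels optional length-2 vector fixing group order
#'   (group 1 first).
#' @param ddd_table DDD reference table.
#' @return Data frame, one comparison per row: `variable`, `type`,
#'   `group1_n`, `group1_stat` (% or mean), `group1_sd`, likewise group 2,
#'   `test`, `p_value`.
#' @export
build_demographics <- function(subjects, partition,
                               group_levels = NULL,
                               ddd_table = default_ddd_table()) {
  grp <- if (length(partition) == 1 && is.character(partition))
    subjects[[partition]] else partition
  if (length(grp) != nrow(subjects))
    stop("partition length does not match subject table", call. = FALSE)
  levels_ <- if (is.null(group_levels)) sort(unique(as.character(grp)))
             else group_levels
  if (length(levels_) != 2 || !all(grp %in% levels_))
    stop("partition must split subjects into exactly two groups",
         call. = FALSE)
  if (min(table(factor(grp, levels = levels_))) == 0)
    stop("a partition group is empty", call. = FALSE)

  rows <- list()
  rows[[length(rows) + 1]] <-
    demog_cat_row("male", subjects$sex == "male", grp, levels_)
  if ("followup_flag" %in% names(subjects))
    rows[[length(rows) + 1]] <-
      demog_cat_row("followup", subjects$followup_flag == 1, grp, levels_)
  for (band in c("le50", "b51_64", "ge65"))
    rows[[length(rows) + 1]] <-
      demog_cat_row(paste0("age_", band), subjects$age_band == band, grp, levels_)

  for (drug in migraine_drugs()) {
    dose_col <- paste0(drug, "_dosage_mg")
    dur_col <- paste0(drug, "_duration_days")
    used <- subjects[[dose_col]] > 0
    rows[[length(rows) + 1]] <-
      demog_cat_row(paste0(drug, "_user"), used, grp, levels_)
    split_vals <- function(v) list(v[used & grp == levels_[1]],
                                   v[used & grp == levels_[2]])
    dose <- subjects[[dose_col]]; dur <- subjects[[dur_col]]
    ddd <- ddd_convert(dose, drug, ddd_table)
    avg_ddd <- ifelse(dur > 0, ddd / dur, 0)
    rows[[length(rows) + 1]] <-
      demog_cont_row(paste0(drug, "_dosage_mg"), split_vals(dose), grp, levels_)
    rows[[length(rows) + 1]] <-
      demog_cont_row(paste0(drug, "_duration_days"), split_vals(dur), grp, levels_)
    rows[[length(rows) + 1]] <-
      demog_cont_row(paste0(drug, "_dosage_ddd"), split_vals(ddd), grp, levels_)
    rows[[length(rows) + 1]] <-
      demog_cont_row(paste0(drug, "_avg_daily_ddd"), split_vals(avg_ddd), grp, levels_)
  }

  out <- do.call(rbind, rows)
  attr(out, "group_levels") <- levels_
  out
}

#' Odds-ratio table for all outcomes over a two-group partition
#'
#' One [odds_ratio()] per `outcome_*` column: group 1 with the outcome vs
#' without, against group 2.
#'
#' @inheritParams build_demographics
#' @return Data frame with one row per outcome: cell counts, OR, CI,
#'   p-value, correction flag.
#' @export
outcome_odds_table <- function(subjects, partition, group_levels = NULL) {
  grp <- if (length(partition) == 1 && is.character(partition))
    subjects[[partition]] else partition
  levels_ <- if (is.null(group_levels)) sort(unique(as.character(grp)))
             else group_levels
  outcome_cols <- grep("^outcome_", names(subjects), value = TRUE)
  rows <- lapply(outcome_cols, function(col) {
    flag <- subjects[[col]] == 1
    a <- sum(flag & grp == levels_[1]); b <- sum(!flag & grp == levels_[1])
    c_ <- sum(flag & grp == levels_[2]); d <- sum(!flag & grp == levels_[2])
    res <- odds_ratio(a, b, c_, d)
    data.frame(outcome = sub("^outcome_", "", col),
               a = a, b = b, c = c_, d = d,
               or = res$or_point, ci_low = res$ci_low, ci_high = res$ci_high,
               p_value = res$p_value,
               correction_applied = res$correction_applied,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "group_levels") <- levels_
  out
}
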