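test_that("generated cohorts have the configured size and match structure", {
  cfg <- cohort_config(n_cases = 100, match_ratio = 5, rng_seed = 7)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 600)
  expect_equal(sum(coh$group == "case"), 100)
  expect_equal(length(unique(coh$match_set_id)), 100)

  # direct scan: every match set has 1 case + 5 controls agreeing on
  # sex, age band and index date
  by_set <- split(coh, coh$match_set_id)
  expect_true(all(vapply(by_set, function(s) {
    nrow(s) == 6 && sum(s$group == "case") == 1 &&
      length(unique(s$sex)) == 1 && length(unique(s$age_band)) == 1 &&
      length(unique(s$index_date)) == 1
  }, logical(1))))

  # exposure invariant: zero dosage iff zero duration
  for (drug in migraine_drugs()) {
    dur <- coh[[paste0(drug, "_duration_days")]]
    dose <- coh[[paste0(drug, "_dosage_mg")]]
    expect_identical(dur == 0, dose == 0)
    expect_true(all(dur >= 0) && all(dose >= 0))
    expect_true(all(dur == round(dur)))
  }
})

test_that("identical configurations reproduce byte-identical cohorts", {
  cfg <- cohort_config(n_cases = 80, rng_seed = 123)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # a different seed changes the draw
  cfg2 <- cohort_config(n_cases = 80, rng_seed = 124)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_cases = 0), "n_cases")
  expect_error(cohort_config(cluster_fractions = c(bulk = 0.5, high_exposure = 0.4)),
               "cluster_fractions")
  expect_error(cohort_config(p_male = 1.4), "p_male")
  oc <- default_outcome_spec_bad <- data.frame(
    outcome = "x", base_rate = 0.05, or_case = -1, or_high_cluster = 1)
  expect_error(cohort_config(outcomes = oc), "or_case")
})

test_that("match_controls enforces strata and index-date inheritance", {
  case <- data.frame(subject_id = "c1", group = "case", sex = "male",
                     age_band = "le50", match_set_id = "c1",
                     index_date = as.Date("2005-06-01"),
                     stringsAsFactors = FALSE)
  pool <- data.frame(subject_id = sprintf("p%d", 1:10), group = "control",
                     sex = "male", age_band = "le50",
                     match_set_id = NA_character_,
                     index_date = as.Date("2004-01-01"),
                     stringsAsFactors = FALSE)
  ctrl <- match_controls(case, pool, ratio = 5, rng_seed = 1)
  expect_equal(nrow(ctrl), 5)
  expect_true(all(ctrl$sex == "male" & ctrl$age_band == "le50"))
  expect_true(all(ctrl$index_date == case$index_date))
  expect_true(all(ctrl$match_set_id == "c1"))
  expect_equal(anyDuplicated(ctrl$subject_id), 0)

  # stratum exhaustion names the deficient stratum
  short_pool <- pool[1:3, ]
  expect_error(match_controls(case, short_pool, ratio = 5),
               "male\\|le50")
})

test_that("feature extraction preserves order, values and shape", {
  coh <- small_cohort(n_cases = 100, seed = 5)
  X <- subjects_to_features(coh)
  expect_equal(dim(X), c(600L, 10L))
  expect_identical(colnames(X), exposure_feature_names())
  # round trip: the feature row equals the subject's exposure record
  i <- which(coh$propranolol_dosage_mg > 0)[1]
  expect_equal(X[i, "propranolol_dosage_mg"], coh$propranolol_dosage_mg[i],
               ignore_attr = TRUE)
  expect_equal(unname(X[i, ]),
               as.numeric(coh[i, exposure_feature_names()]))
  # all-zero exposure subject gives an all-zero row
  j <- which(rowSums(coh[, exposure_feature_names()]) == 0)[1]
  expect_true(all(X[j, ] == 0))
  expect_error(subjects_to_features(coh[0, ]), "empty")
})

test_that("a planted odds ratio of 4 is recovered from the 2x2 counts", {
  oc <- data.frame(outcome = "planted", base_rate = 0.05, or_case = 4.0,
                   or_high_cluster = 1)
  coh <- generate_cohort(cohort_config(n_cases = 20000, outcomes = oc,
                                       rng_seed = 3))
  tab <- outcome_odds_table(coh, coh$group, group_levels = c("case", "control"))
  expect_lt(abs(tab$or - 4.0) / 4.0, 0.15)
})

test_that("default planted outcome effects are recovered within Monte Carlo error", {
  coh <- generate_cohort(cohort_config(n_cases = 20000, rng_seed = 9))
  tab <- outcome_odds_table(coh, coh$group, group_levels = c("case", "control"))
  spec <- merge(tab, comorbscreen:::default_outcome_spec(),
                by = "outcome")
  # Woolf SE of log OR; planted value within 3 standard errors
  se <- sqrt(1 / spec$a + 1 / spec$b + 1 / spec$c + 1 / spec$d)
  expect_true(all(abs(log(spec$or) - log(spec$or_case)) < 3 * se))
})

test_that("the planted high-exposure subcluster is elevated for every drug", {
  coh <- small_cohort(n_cases = 2000, seed = 31)
  cases <- coh[coh$group == "case", ]
  for (drug in migraine_drugs()) {
    col <- paste0(drug, "_dosage_mg")
    expect_gt(mean(cases[cases$true_cluster == "high_exposure", col]),
              mean(cases[cases$true_cluster == "bulk", col]))
  }
})

test_that("the subject table round-trips through delimited text", {
  coh <- small_cohort(n_cases = 40, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_subject_table(coh, path)
  back <- read_subject_table(path)
  expect_equal(back$index_date, coh$index_date)
  expect_equal(back$subject_id, coh$subject_id)
  expect_equal(subjects_to_features(back), subjects_to_features(coh),
               tolerance = 1e-10)
  # header is a plain first line of tab-separated names
  expect_identical(strsplit(readLines(path, n = 1), "\t")[[1]], names(coh))
})
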