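test_that("odds ratio reproduces hand arithmetic, symmetry and reciprocity", {
  expect_equal(odds_ratio(10, 10, 10, 10)$or_point, 1)

  # published amitriptyline utilization cells: 211/19,356 cases vs
  # 335/96,780 controls
  r <- odds_ratio(211, 19145, 335, 96445)
  expect_equal(r$or_point, (211 * 96445) / (19145 * 335), tolerance = 1e-12)
  expect_equal(round(r$or_point, 3), 3.173)

  # swapping case and control rows inverts the OR exactly
  rs <- odds_ratio(335, 96445, 211, 19145)
  expect_equal(rs$or_point, 1 / r$or_point, tolerance = 1e-12)

  expect_error(odds_ratio(0, 0, 5, 5), "margin")
})

test_that("Woolf interval contains the point estimate and shrinks with n", {
  r <- odds_ratio(20, 80, 10, 90)
  expect_lte(r$ci_low, r$or_point)
  expect_gte(r$ci_high, r$or_point)
  # scaling all cells by 10 shrinks the CI around the same point
  r10 <- odds_ratio(200, 800, 100, 900)
  expect_equal(r10$or_point, r$or_point, tolerance = 1e-12)
  expect_lt(r10$ci_high - r10$ci_low, r$ci_high - r$ci_low)
  # hand check of the log-normal interval
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(r$ci_low, exp(log(r$or_point) - qnorm(0.975) * se),
               tolerance = 1e-12)
})

test_that("zero cells trigger the Haldane-Anscombe correction and flag it", {
  r <- odds_ratio(0, 50, 10, 40)
  expect_true(r$correction_applied)
  expect_equal(r$or_point, (0.5 * 40.5) / (50.5 * 10.5), tolerance = 1e-12)
  expect_true(is.finite(r$ci_low) && r$ci_low > 0)
  expect_false(odds_ratio(5, 50, 10, 40)$correction_applied)
})

test_that("chi-square matches the textbook formula and published p = 1.000", {
  # perfectly matched proportions: 5,328/19,356 cases vs 26,640/96,780
  # controls male
  res <- chi_square_2x2(5328, 19356 - 5328, 26640, 96780 - 26640)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-10)

  expect_equal(chi_square_2x2(7, 7, 7, 7)$p_value, 1)

  set.seed(61)
  for (i in 1:10) {
    cells <- rpois(4, 40) + 1
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    n <- a + b + c_ + d
    textbook <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    res <- chi_square_2x2(a, b, c_, d)
    expect_equal(res$statistic, textbook, tolerance = 1e-10)
    expect_equal(res$p_value, pchisq(textbook, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
    # invariance under row swap and column swap
    expect_equal(chi_square_2x2(c_, d, a, b)$statistic, res$statistic,
                 tolerance = 1e-10)
    expect_equal(chi_square_2x2(b, a, d, c_)$statistic, res$statistic,
                 tolerance = 1e-10)
  }
})

test_that("two-sample t test behaves at identity, power and antisymmetry", {
  x <- c(1, 2, 3, 4, 5)
  res <- two_sample_t(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(62)
  a <- rnorm(10000); b <- rnorm(10000, 1)
  expect_lt(two_sample_t(a, b)$p_value, 0.001)
  expect_equal(two_sample_t(a, b)$statistic, -two_sample_t(b, a)$statistic,
               tolerance = 1e-12)
  expect_error(two_sample_t(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("DDD conversion is linear and anchored to the reference table", {
  expect_equal(ddd_convert(0, "propranolol"), 0)
  tab <- default_ddd_table()
  for (i in seq_len(nrow(tab)))
    expect_equal(ddd_convert(tab$mg_per_ddd[i], tab$drug[i]), 1)
  expect_equal(ddd_convert(750, "amitriptyline"), 10)
  expect_equal(ddd_convert(2 * 123, "flunarizine"),
               2 * ddd_convert(123, "flunarizine"), tolerance = 1e-12)
  # average daily dose divides by treatment days
  expect_equal(ddd_convert(320, "propranolol", duration_days = 10), 0.2)
  expect_error(ddd_convert(10, "aspirin"), "aspirin")
})

test_that("proportions reproduce published table percentages", {
  expect_equal(round_half_up(proportion(5328, 19356)), 27.5)
  expect_equal(round_half_up(proportion(3664, 19356)), 18.9)
  expect_equal(round_half_up(proportion(13530, 19356)), 69.9)
  expect_equal(proportion(0, 50), 0)
  expect_error(proportion(1, 0), "total")
  expect_error(proportion(5, 3), "count")
})

test_that("demographics tables agree with direct recomputation", {
  coh <- small_cohort(n_cases = 400, seed = 63)
  tab <- build_demographics(coh, coh$group, group_levels = c("case", "control"))

  male_row <- tab[tab$variable == "male", ]
  expect_equal(male_row$group1_n, sum(coh$sex == "male" & coh$group == "case"))
  expect_equal(male_row$group1_stat,
               proportion(male_row$group1_n, sum(coh$group == "case")))

  # continuous rows are computed among utilizers only
  drug_row <- tab[tab$variable == "propranolol_dosage_mg", ]
  users <- coh$propranolol_dosage_mg > 0
  expect_equal(drug_row$group1_stat,
               mean(coh$propranolol_dosage_mg[users & coh$group == "case"]))
  expect_equal(drug_row$group1_sd,
               sd(coh$propranolol_dosage_mg[users & coh$group == "case"]))
  expect_equal(drug_row$group1_n, sum(users & coh$group == "case"))

  # DDD rows equal the mg rows divided by the reference constant
  ddd_row <- tab[tab$variable == "propranolol_dosage_ddd", ]
  expect_equal(ddd_row$group1_stat, drug_row$group1_stat / 160,
               tolerance = 1e-12)

  # identical groups: categorical p-values are all 1
  dup <- rbind(coh, coh)
  grp <- rep(c("g1", "g2"), each = nrow(coh))
  tab2 <- build_demographics(dup, grp)
  expect_true(all(abs(tab2$p_value[tab2$type == "categorical"] - 1) < 1e-9,
                  na.rm = TRUE))

  expect_error(build_demographics(coh, rep("onlygroup", nrow(coh))),
               "two groups")
})
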