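test_that("TaT counts days inclusively with the same-day convention", {
  cases <- validate_cases(toy_cases())$cases
  # same day -> 1; 1 Mar to 9 Mar -> 9; across the Jan/Feb boundary -> 4
  expect_equal(tat_days(cases)[1:3], c(1L, 9L, 4L))
  bad <- cases
  bad$report_date[1] <- bad$receipt_date[1] - 2
  expect_error(tat_days(bad), "negative")
})

test_that("summaries match direct formulas", {
  df <- random_cases(5)
  df$report_date <- df$receipt_date + c(0, 1, 2, 3, 4)  # TaT 1..5
  s <- summarize_tat(validate_cases(df)$cases)
  expect_equal(s$mean, 3); expect_equal(s$median, 3)
  expect_equal(s$q25, 2); expect_equal(s$q75, 4)

  one <- summarize_tat(validate_cases(df[3, ])$cases)
  expect_equal(one$mean, 3); expect_equal(one$median, 3)
  expect_true(is.na(one$sd) || one$sd == 0)

  # 200-value sample against the independently coded brute force
  set.seed(99)
  df <- random_cases(200)
  s <- summarize_tat(validate_cases(df)$cases)
  o <- brute_force_summary(as.integer(df$report_date - df$receipt_date) + 1L)
  for (f in c("n", "mean", "sd", "median", "q25", "q75", "min", "max")) {
    expect_equal(s[[f]], o[[f]], tolerance = 1e-12, label = f)
  }
})

test_that("stratified summaries cover each non-empty stratum", {
  cases <- validate_cases(toy_cases())$cases
  s <- summarize_tat(cases, "pathologist")
  expect_named(s, c("A", "B"))
  expect_equal(s$A$n + s$B$n, nrow(cases))
  tab <- tat_summary_table(s)
  expect_equal(tab$stratum, c("A", "B"))
})

test_that("small-sample U test matches exact enumeration", {
  cmp <- compare_tat(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$u_statistic, 0)
  expect_equal(cmp$u_pvalue, 0.1)   # 2 / choose(6, 3) extreme assignments

  same <- compare_tat(c(5, 5, 5, 6), c(5, 5, 5, 6))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$median_difference, 0)

  degen <- compare_tat(c(4, 4), c(4, 4))
  expect_true(degen$degenerate)
  expect_equal(degen$u_pvalue, 1)
  expect_true(is.na(degen$t_statistic))
})

test_that("differences are exact arithmetic and antisymmetric", {
  set.seed(1)
  x <- sample(1:30, 40, replace = TRUE)
  y <- sample(1:20, 50, replace = TRUE)
  ab <- compare_tat(x, y)
  ba <- compare_tat(y, x)
  expect_equal(ab$mean_difference, ab$summary_cm$mean - ab$summary_dp$mean)
  expect_equal(ab$mean_difference, -ba$mean_difference)
  expect_equal(ab$median_difference, -ba$median_difference)
  # the two-sided p-values do not depend on argument order
  expect_equal(ab$t_pvalue, ba$t_pvalue)
  expect_equal(ab$u_pvalue, ba$u_pvalue)
})

test_that("normal approximation tracks exact enumeration at n = 6 + 6", {
  set.seed(42)
  worst <- 0
  for (i in 1:40) {
    x <- sample(1:10000, 6)   # continuous-like, no ties
    y <- sample(setdiff(1:10000, x), 6)
    pe <- pathflow:::.u_exact_p(x, y)
    pn <- pathflow:::.u_normal_p(x, y)
    worst <- max(worst, abs(pe - pn))
  }
  expect_lt(worst, 0.02)
})

test_that("U statistic and approximate p agree with wilcox.test under ties", {
  set.seed(8)
  for (i in 1:20) {
    x <- sample(1:8, 25, replace = TRUE)
    y <- sample(1:10, 30, replace = TRUE)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    expect_equal(pathflow:::.u_statistic(x, y), unname(wt$statistic))
    expect_equal(pathflow:::.u_normal_p(x, y), wt$p.value, tolerance = 1e-10)
  }
})

test_that("slide-count association has the right sign and null behaviour", {
  df <- random_cases(8)
  df$slide_category <- rep(c("1", "2", "3-4", ">=5"), each = 2)
  df$report_date <- df$receipt_date + c(1, 1, 3, 3, 6, 6, 9, 9)
  co <- validate_cases(df)$cases
  expect_equal(slide_association(co)$rho, 1)

  df$report_date <- df$receipt_date + c(9, 9, 6, 6, 3, 3, 1, 1)
  expect_equal(slide_association(validate_cases(df)$cases)$rho, -1)

  # independence by construction in the generator
  big <- quick_cohort(cohort_spec(n_cm = 1500, n_dp = 1500, seed = 3))
  expect_lt(abs(slide_association(big)$rho), 0.1)

  # constant TaT -> undefined, flagged
  df$report_date <- df$receipt_date + 2
  expect_false(slide_association(validate_cases(df)$cases)$defined)
})

test_that("the contingency utility compares categorical composition", {
  big <- quick_cohort(cohort_spec(n_cm = 800, n_dp = 800, seed = 21))
  res <- compare_composition(big, "slide_category")
  expect_equal(dim(res$table), c(2L, 4L))
  expect_true(res$p_value > 0 && res$p_value <= 1)
})
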