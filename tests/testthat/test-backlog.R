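test_that("the half-open pending convention holds at the boundaries", {
  df <- random_cases(1)
  df$pathologist <- "A"
  df$receipt_date <- as.Date("2021-01-10")
  df$report_date <- as.Date("2021-01-12")
  pm <- pending_matrix(validate_cases(df)$cases, 2021)
  expect_equal(sum(pm[, "A"]), 2)                    # days 10 and 11 only
  expect_equal(unname(pm[10:12, "A"]), c(1L, 1L, 0L))
  expect_equal(sum(pm[, "B"]), 0)

  # TaT = 1 contributes zero backlog
  df$report_date <- df$receipt_date
  pm1 <- pending_matrix(validate_cases(df)$cases, 2021)
  expect_equal(sum(pm1), 0)

  # empty record set -> all-zero matrix
  pm0 <- pending_matrix(validate_cases(df[0, ])$cases, 2021)
  expect_equal(sum(pm0), 0)
  expect_equal(dim(pm0), c(365L, 2L))
})

test_that("sweep line equals brute force exhaustively on small instances", {
  # every subset of a pool of interval shapes, up to 20 cases
  pool <- expand.grid(start = c(1, 50, 360, 364), tat = c(1, 2, 10, 40))
  df <- random_cases(nrow(pool))
  df$receipt_date <- as.Date("2021-01-01") + (pool$start - 1)
  df$report_date <- df$receipt_date + (pool$tat - 1)
  df$pathologist <- rep(c("A", "B"), length.out = nrow(df))
  for (k in c(1, 3, 7, 16)) {
    idx <- utils::combn(nrow(df), k)[, 1:min(20, choose(nrow(df), k)),
                                     drop = FALSE]
    for (j in seq_len(ncol(idx))) {
      sub <- validate_cases(df[idx[, j], ])$cases
      pm <- pending_matrix(sub, 2021)
      expect_equal(unclass(pm)[, ], brute_force_census(sub, 2021),
                   ignore_attr = TRUE)
    }
  }
})

test_that("sweep line equals brute force on random cohorts", {
  set.seed(12)
  for (i in 1:10) {
    df <- validate_cases(random_cases(500, max_tat = 50))$cases
    pm <- pending_matrix(df, 2021)
    expect_equal(unclass(pm)[, ], brute_force_census(df, 2021),
                 ignore_attr = TRUE)
  }
})

test_that("pending-days are conserved, including year-end clipping", {
  set.seed(3)
  df <- validate_cases(random_cases(300, max_tat = 60))$cases
  pm <- pending_matrix(df, 2021)
  jan1_next <- as.Date("2022-01-01")
  for (p in c("A", "B")) {
    sub <- df[df$pathologist == p, ]
    expected <- sum(pmax(
      as.integer(pmin(sub$report_date, jan1_next) - sub$receipt_date), 0))
    expect_equal(sum(pm[, p]), expected)
  }
})

test_that("adding a case never decreases any count", {
  set.seed(4)
  df <- validate_cases(random_cases(50))$cases
  pm_all <- pending_matrix(df, 2021)
  pm_less <- pending_matrix(df[-1, ], 2021)
  expect_true(all(unclass(pm_all) >= unclass(pm_less)))
})

test_that("backlog summaries report means, peaks and first peak date", {
  df <- random_cases(1)
  df$pathologist <- "A"
  df$receipt_date <- as.Date("2021-05-01")
  df$report_date <- as.Date("2021-05-03")
  s <- summarize_backlog(pending_matrix(validate_cases(df)$cases, 2021))
  expect_equal(s$mean_daily_pending[s$pathologist == "A"], 2 / 365)
  expect_equal(s$peak_count[s$pathologist == "A"], 1)
  expect_equal(s$peak_date[s$pathologist == "A"], as.Date("2021-05-01"))
  expect_equal(s$peak_count[s$pathologist == "B"], 0)

  # oracle recomputation on a generated cohort
  co <- quick_cohort(cohort_spec(n_cm = 400, n_dp = 10, seed = 6))
  cm <- co[co$methodology == "CM", ]
  s2 <- summarize_backlog(pending_matrix(cm, 2021))
  bf <- brute_force_census(cm, 2021)
  expect_equal(s2$mean_daily_pending, unname(colMeans(bf)))
  expect_equal(s2$peak_count, unname(apply(bf, 2, max)))
})

test_that("backlog comparison is exact arithmetic and antisymmetric", {
  set.seed(9)
  a <- summarize_backlog(pending_matrix(validate_cases(random_cases(200))$cases, 2021))
  b <- summarize_backlog(pending_matrix(validate_cases(random_cases(150))$cases, 2021))
  ab <- compare_backlogs(a, b)
  ba <- compare_backlogs(b, a)
  expect_equal(ab$per_pathologist$reduction, -ba$per_pathologist$reduction)
  expect_equal(ab$average, -ba$average)
  expect_equal(compare_backlogs(a, a)$average, 0)

  onlyA <- a[a$pathologist == "A", ]
  class(onlyA) <- class(a)
  expect_error(compare_backlogs(onlyA, b), "pathologist sets")
})
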