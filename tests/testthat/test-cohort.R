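test_that("calibrated distributions hit their summary targets", {
  d <- cached_dists()
  for (grp in names(d)) {
    dist <- d[[grp]]
    t <- dist$target
    # independent oracle: direct summation over the full discrete support
    p <- dist$pmf
    k <- dist$support
    expect_equal(sum(p), 1, tolerance = 1e-12)
    m <- sum(k * p)
    s <- sqrt(sum((k - m)^2 * p))
    expect_lt(abs(m - t$mean), 0.1)
    expect_lt(abs(s - t$sd), 0.2)
    # quantiles: linear interpolation of the CDF anchored at F(0) = 0
    Fk <- c(0, cumsum(p))
    oq <- function(pp) {
      j <- which(Fk >= pp)[1] - 1L
      (j - 1L) + (pp - Fk[j]) / (Fk[j + 1L] - Fk[j])
    }
    expect_lt(abs(oq(0.25) - t$q25), 1)
    expect_lt(abs(oq(0.50) - t$median), 1)
    expect_lt(abs(oq(0.75) - t$q75), 1)
    # reported discrepancies are what the oracle measures
    expect_equal(unname(dist$discrepancy["mean"]), m - t$mean, tolerance = 1e-8)
  }
})

test_that("a near-degenerate target yields a near-point-mass", {
  d <- calibrate_tat_distribution(tat_target(5, 0.1, 5, 5, 5, 1, 20))
  expect_gt(d$pmf[5], 0.95)
  expect_equal(sum(d$support * d$pmf), 5, tolerance = 0.1)
})

test_that("infeasible targets fail with a calibration signal", {
  # quartile spread far wider than the SD allows
  expect_error(
    calibrate_tat_distribution(tat_target(10, 0.2, 10, 3, 25, 1, 40)),
    class = "pathflow_calibration_error"
  )
})

test_that("cohort generation is deterministic and respects the spec", {
  spec <- cohort_spec(n_cm = 300, n_dp = 200, seed = 77)
  a <- quick_cohort(spec)
  b <- quick_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 500)
  expect_equal(sum(a$methodology == "CM"), 300)
  expect_equal(sum(a$methodology == "DP"), 200)
  # group years
  expect_true(all(format(a$receipt_date[a$methodology == "CM"], "%Y") == "2021"))
  expect_true(all(format(a$receipt_date[a$methodology == "DP"], "%Y") == "2022"))
  # a different seed moves the draw
  expect_false(identical(a, quick_cohort(cohort_spec(n_cm = 300, n_dp = 200,
                                                     seed = 78))))
  # TaT support bounds hold
  tat <- as.integer(a$report_date - a$receipt_date) + 1L
  expect_true(all(tat >= 1))
  expect_true(all(tat[a$methodology == "CM"] <= spec$tat_target_cm$max))
  expect_true(all(tat[a$methodology == "DP"] <= spec$tat_target_dp$max))
})

test_that("tiny cohorts hit the degenerate boundary cleanly", {
  a <- quick_cohort(cohort_spec(n_cm = 1, n_dp = 1, seed = 5))
  expect_equal(nrow(a), 2)
  expect_setequal(as.character(a$methodology), c("CM", "DP"))
  expect_error(cohort_spec(n_cm = 0))
})

test_that("categorical frequencies converge to their probabilities", {
  spec <- cohort_spec(n_cm = 2000, n_dp = 2000, seed = 31)
  a <- quick_cohort(spec)
  n <- nrow(a)
  for (i in seq_along(spec$slide_probs)) {
    p <- spec$slide_probs[i]
    phat <- mean(a$slide_category == names(spec$slide_probs)[i])
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  }
  pA <- mean(a$pathologist == "A")
  expect_lt(abs(pA - 0.5), 3 * sqrt(0.25 / n))
})

test_that("monthly volumes show the summer dip", {
  w <- default_monthly_weights()
  expect_equal(sum(w), 1)
  expect_lt(w[7] + w[8], 2 / 12)             # below the uniform share
  a <- quick_cohort(cohort_spec(n_cm = 3000, n_dp = 10, seed = 13))
  m <- as.integer(format(a$receipt_date[a$methodology == "CM"], "%m"))
  counts <- tabulate(m, 12)
  # each month within 4 binomial sigmas of its weight
  for (i in 1:12) {
    expect_lt(abs(counts[i] - 3000 * w[i]),
              4 * sqrt(3000 * w[i] * (1 - w[i])) + 1)
  }
})

test_that("cohort specs round-trip through config files", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_cm = 120, n_dp = 90, seed = 9,
                        tat_target_dp = list(mean = 6.86, sd = 5.10, median = 5,
                                             q25 = 3, q75 = 9, min = 1, max = 44)),
                   cfg)
  spec <- cohort_spec_from_config(cfg)
  expect_equal(spec$n_cm, 120L)
  expect_equal(spec$n_dp, 90L)
  expect_equal(spec$seed, 9L)
  expect_equal(spec$tat_target_dp$max, 44)
})
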