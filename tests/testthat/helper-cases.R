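# Shared fixtures and independent oracles, all built in code.

# A small handmade, fully valid case table.
toy_cases <- function() {
  data.frame(
    case_id = sprintf("T-%03d", 1:6),
    receipt_date = as.Date(c("2021-03-01", "2021-03-01", "2021-01-30",
                             "2021-06-10", "2022-02-14", "2022-11-30")),
    report_date = as.Date(c("2021-03-01", "2021-03-09", "2021-02-02",
                            "2021-06-15", "2022-02-20", "2022-12-05")),
    pathologist = c("A", "B", "A", "B", "A", "B"),
    methodology = c("CM", "CM", "CM", "CM", "DP", "DP"),
    slide_category = c("1", "2", "3-4", ">=5", "1", "2"),
    area = c("dermatopathology", "other", "complex-digestive",
             "neuropathology", "gynaecology-uropathology",
             "head-neck-endocrine"),
    stringsAsFactors = FALSE
  )
}

# Calibrating the default TaT distributions takes a few seconds; memoize
# them for the whole test run.
.dist_cache <- new.env(parent = emptyenv())
cached_dists <- function() {
  if (is.null(.dist_cache$cm)) {
    spec <- cohort_spec()
    .dist_cache$cm <- calibrate_tat_distribution(spec$tat_target_cm)
    .dist_cache$dp <- calibrate_tat_distribution(spec$tat_target_dp)
  }
  list(cm = .dist_cache$cm, dp = .dist_cache$dp)
}

# Generate a cohort reusing the cached calibrations.
quick_cohort <- function(spec = cohort_spec()) {
  d <- cached_dists()
  generate_cohort(spec, dist_cm = d$cm, dist_dp = d$dp)
}

# Independent brute-force census oracle: for every day of the year, count
# cases with receipt <= day < report, one pathologist at a time.
brute_force_census <- function(cases, year, pathologists = c("A", "B")) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  sapply(pathologists, function(p) {
    sub <- cases[cases$pathologist == p, ]
    vapply(dates, function(d) {
      sum(sub$receipt_date <= d & d < sub$report_date)
    }, numeric(1))
  })
}

# Independent summary oracle: sort + direct textbook formulas.
brute_force_summary <- function(x) {
  x <- sort(x)
  n <- length(x)
  qq <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  }
  list(n = n, mean = sum(x) / n,
       sd = sqrt(sum((x - sum(x) / n)^2) / (n - 1)),
       median = qq(0.5), q25 = qq(0.25), q75 = qq(0.75),
       min = x[1], max = x[n])
}

# Random case table with receipt dates in `year`, for oracle checks.
random_cases <- function(n, year = 2021, max_tat = 30) {
  start <- as.Date(sprintf("%d-01-01", year))
  receipt <- start + sample(0:364, n, replace = TRUE)
  tat <- sample(1:max_tat, n, replace = TRUE)
  data.frame(
    case_id = sprintf("R-%05d", seq_len(n)),
    receipt_date = receipt,
    report_date = receipt + tat - 1L,
    pathologist = sample(c("A", "B"), n, replace = TRUE),
    methodology = "CM",
    slide_category = sample(c("1", "2", "3-4", ">=5"), n, replace = TRUE),
    area = sample(c("dermatopathology", "other"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
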