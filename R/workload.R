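# Workload calendar: pending census relative to theoretical capacity.

#' Theoretical daily diagnostic capacity parameters
#'
#' The theoretical number of diagnoses per day is the annual caseload
#' assigned to a pathologist divided by their annual working days.  Roughly
#' 60% of a pathologist's working time goes to case diagnosis; the fraction
#' does not enter the capacity ratio itself but is carried alongside so the
#' workload index can also be reported as a share of the working day.
#'
#' @param annual_cases_assigned cases to be diagnosed in the year.
#' @param annual_working_days working days per year (default 220).
#' @param diagnostic_time_fraction share of working time spent diagnosing
#'   (default 0.60).
#' @return object of class `capacity_params`.
#' @export
capacity_params <- function(annual_cases_assigned,
                            annual_working_days = 220L,
                            diagnostic_time_fraction = 0.60) {
  stopifnot(annual_working_days > 0,
            diagnostic_time_fraction > 0, diagnostic_time_fraction <= 1,
            annual_cases_assigned >= 0)
  structure(list(annual_cases_assigned = annual_cases_assigned,
                 annual_working_days = annual_working_days,
                 diagnostic_time_fraction = diagnostic_time_fraction),
            class = "capacity_params")
}

#' Theoretical diagnoses per working day
#'
#' @param params a [capacity_params()].
#' @return cases per working day; 0 (with a warning) when no cases are
#'   assigned.
#' @export
theoretical_daily_diagnoses <- function(params) {
  stopifnot(inherits(params, "capacity_params"))
  cap <- params$annual_cases_assigned / params$annual_working_days
  if (cap == 0) warning("zero assigned cases: degenerate capacity 0")
  cap
}

#' Workload calendar from a pending census
#'
#' The workload index on day d for pathologist p is the pending count
#' divided by that pathologist's theoretical daily diagnoses; an index
#' above 1 means the backlog exceeds a day's diagnostic capacity.
#'
#' @param matrix a [pending_matrix()].
#' @param params named list of [capacity_params()], one per pathologist
#'   column of the matrix (or a single `capacity_params` applied to all).
#' @return object of class `workload_calendar`: data.frame with columns
#'   `date`, `month`, `pathologist`, `pending`, `capacity`, `index`, and
#'   `day_share` (the index divided by the diagnostic time fraction: the
#'   share of a full working day the backlog represents).
#' @export
workload_calendar <- function(matrix, params) {
  stopifnot(inherits(matrix, "pending_matrix"))
  if (inherits(params, "capacity_params")) {
    params <- stats::setNames(rep(list(params), ncol(matrix)), colnames(matrix))
  }
  stopifnot(all(colnames(matrix) %in% names(params)))
  dates <- attr(matrix, "dates")
  out <- do.call(rbind, lapply(colnames(matrix), function(p) {
    cap <- theoretical_daily_diagnoses(params[[p]])
    if (cap <= 0) stop("capacity must be positive for pathologist ", p)
    data.frame(
      date = format(dates, "%Y-%m-%d"),
      month = as.integer(format(dates, "%m")),
      pathologist = p,
      pending = as.integer(matrix[, p]),
      capacity = cap,
      index = matrix[, p] / cap,
      day_share = matrix[, p] / cap * params[[p]]$diagnostic_time_fraction,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  structure(out, year = attr(matrix, "year"),
            class = c("workload_calendar", "data.frame"))
}

#' Year-over-year workload reduction
#'
#' Percent reduction in the mean workload index of the second calendar
#' relative to the first, `100 * (1 - mean(index_b) / mean(index_a))`,
#' averaged over days (optionally a subset of months, matched calendar
#' month against calendar month) and unweighted across pathologists.  A
#' per-month reduction table is returned alongside.
#'
#' @param cal_a,cal_b `workload_calendar` objects for the two years
#'   (conventionally microscopy year first, so a positive reduction means
#'   the digital year is lighter).
#' @param months optional integer vector of months (1-12) to restrict to.
#' @return list with `reduction_pct`, `monthly` (data.frame of per-month
#'   reductions) and the two period means.
#' @export
workload_reduction <- function(cal_a, cal_b, months = NULL) {
  stopifnot(inherits(cal_a, "workload_calendar"),
            inherits(cal_b, "workload_calendar"))
  if (!setequal(unique(cal_a$pathologist), unique(cal_b$pathologist))) {
    stop("workload calendars cover different pathologist sets")
  }
  sel <- function(cal) if (is.null(months)) cal else cal[cal$month %in% months, ]
  a <- sel(cal_a); b <- sel(cal_b)
  mean_a <- mean(a$index); mean_b <- mean(b$index)
  if (mean_a == 0) {
    warning("zero mean workload in the reference period: reduction undefined")
    red <- NA_real_
  } else {
    red <- 100 * (1 - mean_b / mean_a)
  }
  monthly <- do.call(rbind, lapply(sort(unique(cal_a$month)), function(m) {
    ma <- mean(cal_a$index[cal_a$month == m])
    mb <- mean(cal_b$index[cal_b$month == m])
    data.frame(month = m, mean_index_a = ma, mean_index_b = mb,
               reduction_pct = if (ma > 0) 100 * (1 - mb / ma) else NA_real_)
  }))
  list(reduction_pct = red, monthly = monthly,
       mean_index_a = mean_a, mean_index_b = mean_b)
}
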