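# Daily pending-cases census.
#
# A case is pending on day d iff receipt_date <= d < report_date: pending
# on its receipt day, no longer pending on its report day, so a same-day
# sign-out (TaT = 1) contributes zero backlog.  The census is computed by a
# sweep line (+1 at receipt, -1 at report, prefix sums), which the test
# suite checks against brute-force day-by-day counting.

#' Daily pending-cases matrix for one calendar year
#'
#' For each day of `year` and each pathologist, counts the cases received
#' but not yet reported under the half-open convention
#' `receipt <= day < report`.  Cases still open past December 31 remain
#' pending through year end; intervals are clipped to the year window.
#' Weekends and holidays are ordinary days.
#'
#' @param cases validated case data.frame.
#' @param year calendar year of the census.
#' @param pathologists pathologist labels defining the columns (defaults to
#'   A and B); an empty record set yields an all-zero matrix.
#' @return object of class `pending_matrix`: an integer matrix with one row
#'   per calendar day and one column per pathologist, with attributes
#'   `year` and `dates`.
#' @export
pending_matrix <- function(cases, year, pathologists = PATHOLOGISTS) {
  year <- as.integer(year)
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  n_days <- length(dates)
  counts <- matrix(0L, nrow = n_days, ncol = length(pathologists),
                   dimnames = list(format(dates, "%Y-%m-%d"), pathologists))
  if (nrow(cases) > 0L) {
    day0 <- dates[1]
    start <- pmax(as.integer(as.Date(cases$receipt_date) - day0) + 1L, 1L)
    end_excl <- pmin(as.integer(as.Date(cases$report_date) - day0) + 1L,
                     n_days + 1L)
    for (j in seq_along(pathologists)) {
      sel <- cases$pathologist == pathologists[j] & end_excl > start &
        start <= n_days & end_excl >= 1L
      diffarr <- integer(n_days + 1L)
      s <- start[sel]; e <- end_excl[sel]
      for (i in seq_along(s)) {
        diffarr[s[i]] <- diffarr[s[i]] + 1L
        diffarr[e[i]] <- diffarr[e[i]] - 1L
      }
      counts[, j] <- cumsum(diffarr[seq_len(n_days)])
    }
  }
  structure(counts, year = year, dates = dates, class = "pending_matrix")
}

#' @export
print.pending_matrix <- function(x, ...) {
  cat(sprintf("Pending-cases census, %d (%d days x %d pathologists)\n",
              attr(x, "year"), nrow(x), ncol(x)))
  for (p in colnames(x)) {
    cat(sprintf("  %s: mean %.2f, peak %d\n", p, mean(x[, p]), max(x[, p])))
  }
  invisible(x)
}

#' Summarize a pending-cases matrix
#'
#' Per pathologist: the mean daily pending count over all days of the year,
#' the maximum count, and the first date attaining it.
#'
#' @param matrix a [pending_matrix()].
#' @return object of class `backlog_summary`: data.frame with columns
#'   `pathologist`, `mean_daily_pending`, `peak_count`, `peak_date`.
#' @export
summarize_backlog <- function(matrix) {
  stopifnot(inherits(matrix, "pending_matrix"))
  dates <- attr(matrix, "dates")
  out <- data.frame(
    pathologist = colnames(matrix),
    mean_daily_pending = colMeans(matrix),
    peak_count = apply(matrix, 2, max),
    peak_date = as.Date(vapply(colnames(matrix), function(p) {
      format(dates[which.max(matrix[, p])], "%Y-%m-%d")
    }, character(1))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, year = attr(matrix, "year"),
            class = c("backlog_summary", "data.frame"))
}

#' Reduction in mean daily pending cases between two censuses
#'
#' `reduction = mean_daily_pending(a) - mean_daily_pending(b)` per
#' pathologist (positive when `b` carries less backlog), plus the unweighted
#' across-pathologist average.
#'
#' @param a,b `backlog_summary` objects over the same pathologist set
#'   (typically the microscopy year and the digital year).
#' @return list with `per_pathologist` (data.frame) and `average`.
#' @export
compare_backlogs <- function(a, b) {
  stopifnot(inherits(a, "backlog_summary"), inherits(b, "backlog_summary"))
  if (!setequal(a$pathologist, b$pathologist)) {
    stop("backlog summaries cover different pathologist sets")
  }
  b <- b[match(a$pathologist, b$pathologist), ]
  red <- a$mean_daily_pending - b$mean_daily_pending
  list(
    per_pathologist = data.frame(pathologist = a$pathologist,
                                 reduction = red, stringsAsFactors = FALSE),
    average = mean(red)
  )
}

#' Export a pending matrix in long format
#'
#' @param matrix a [pending_matrix()].
#' @return data.frame with columns `date`, `pathologist`, `pending_count`.
#' @export
pending_long <- function(matrix) {
  dates <- attr(matrix, "dates")
  data.frame(
    date = rep(format(dates, "%Y-%m-%d"), times = ncol(matrix)),
    pathologist = rep(colnames(matrix), each = nrow(matrix)),
    pending_count = as.integer(matrix),
    stringsAsFactors = FALSE
  )
}
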