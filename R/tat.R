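# Turnaround-time summaries and the two-group comparison.

#' Turnaround time of each case, in days
#'
#' TaT is the time from receipt of the sample to issuance of the diagnostic
#' report, counted inclusively: `(report_date - receipt_date) + 1`, so a
#' same-day report is 1 day and TaT is always >= 1.
#'
#' @param cases validated case data.frame.
#' @return integer vector of days.
#' @export
tat_days <- function(cases) {
  stopifnot(all(c("receipt_date", "report_date") %in% names(cases)))
  d <- as.integer(as.Date(cases$report_date) - as.Date(cases$receipt_date)) + 1L
  if (any(d < 1L, na.rm = TRUE)) stop("negative receipt-to-report interval")
  d
}

.tat_summary_one <- function(x) {
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n = length(x), mean = mean(x), sd = stats::sd(x),
                 median = q[2], q25 = q[1], q75 = q[3],
                 min = min(x), max = max(x)),
            class = "tat_summary")
}

#' @export
print.tat_summary <- function(x, ...) {
  cat(sprintf("n=%d  mean (SD) %.2f (%.2f)  median [IQR] %.2f [%.2f-%.2f]  range %g-%g\n",
              x$n, x$mean, if (is.na(x$sd)) 0 else x$sd,
              x$median, x$q25, x$q75, x$min, x$max))
  invisible(x)
}

#' Summarize TaT, optionally per stratum
#'
#' Computes n, mean, SD, median, quartiles (linear interpolation between
#' order statistics, R type 7) and range of TaT, either overall or for each
#' level of a stratification variable (`pathologist`, `slide_category`,
#' `area`, `methodology`).  Empty strata are omitted with a message.
#'
#' @param cases validated case data.frame.
#' @param by optional column name to stratify on.
#' @return a single `tat_summary` if `by` is `NULL`, else a named list of
#'   them, one per non-empty stratum.
#' @export
summarize_tat <- function(cases, by = NULL) {
  tat <- tat_days(cases)
  if (is.null(by)) return(.tat_summary_one(tat))
  stopifnot(by %in% names(cases))
  g <- cases[[by]]
  out <- list()
  for (lev in levels(factor(g))) {
    idx <- which(g == lev)
    if (length(idx) == 0L) {
      message("stratum '", lev, "' of ", by, " is empty; omitted")
      next
    }
    out[[lev]] <- .tat_summary_one(tat[idx])
  }
  out
}

#' Flatten TaT summaries to a data.frame
#'
#' @param s a `tat_summary` or named list of them.
#' @return data.frame with one row per summary.
#' @export
tat_summary_table <- function(s) {
  if (inherits(s, "tat_summary")) s <- list(overall = s)
  do.call(rbind, lapply(names(s), function(nm) {
    data.frame(stratum = nm, n = s[[nm]]$n, mean = s[[nm]]$mean,
               sd = s[[nm]]$sd, median = s[[nm]]$median, q25 = s[[nm]]$q25,
               q75 = s[[nm]]$q75, min = s[[nm]]$min, max = s[[nm]]$max,
               stringsAsFactors = FALSE)
  }))
}

# Mann-Whitney U (rank-sum form): number of (x, y) pairs with x > y plus
# half the ties.  Computed from midranks so it is exact under ties.
.u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Exact two-sided permutation p-value of U: proportion of the
# choose(n1+n2, n1) group assignments whose U deviates from its null mean
# n1*n2/2 at least as much as the observed one.  Valid under ties.
.u_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  mu <- n1 * n2 / 2
  obs <- abs(.u_statistic(x, y) - mu)
  combos <- utils::combn(n1 + n2, n1)
  devs <- apply(combos, 2, function(idx) {
    abs(.u_statistic(pooled[idx], pooled[-idx]) - mu)
  })
  mean(devs >= obs - 1e-9)
}

# Tie-corrected normal approximation with continuity correction; its
# agreement with exact enumeration is asserted by the test suite.
.u_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  u <- .u_statistic(x, y)
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- max(abs(u - n1 * n2 / 2) - 0.5, 0) / sqrt(sigma2)
  min(2 * stats::pnorm(-z), 1)
}

#' Compare TaT between two groups
#'
#' Computes the mean and median differences (first group minus second),
#' Welch's unequal-variance t test, and the Mann--Whitney U test.  The U
#' test uses exact enumeration over all group assignments when
#' `n1 + n2 <= exact_max` and the tie-corrected normal approximation
#' otherwise.  When every value in both groups is identical the t statistic
#' is undefined; the result is flagged (`degenerate = TRUE`) with U p-value
#' 1 rather than an error.
#'
#' @param cm,dp numeric vectors of TaT days for the two groups (each
#'   n >= 2); conventionally the microscopy group first, so positive
#'   differences mean the digital workflow is faster.
#' @param exact_max largest pooled size for exact U enumeration.
#' @return object of class `tat_comparison`.
#' @examples
#' cmp <- compare_tat(c(9, 12, 8, 15), c(5, 6, 4, 7))
#' cmp$mean_difference
#' @export
compare_tat <- function(cm, dp, exact_max = 12L) {
  stopifnot(length(cm) >= 2L, length(dp) >= 2L)
  s_cm <- .tat_summary_one(cm)
  s_dp <- .tat_summary_one(dp)
  degenerate <- length(unique(c(cm, dp))) == 1L
  if (degenerate) {
    t_stat <- NA_real_; t_p <- NA_real_
  } else {
    tt <- stats::t.test(cm, dp, var.equal = FALSE)
    t_stat <- unname(tt$statistic); t_p <- tt$p.value
  }
  u <- .u_statistic(cm, dp)
  u_p <- if (degenerate) 1
         else if (length(cm) + length(dp) <= exact_max) .u_exact_p(cm, dp)
         else .u_normal_p(cm, dp)
  structure(list(
    summary_cm = s_cm, summary_dp = s_dp,
    mean_difference = s_cm$mean - s_dp$mean,
    median_difference = s_cm$median - s_dp$median,
    t_statistic = t_stat, t_pvalue = t_p,
    u_statistic = u, u_pvalue = u_p,
    degenerate = degenerate
  ), class = "tat_comparison")
}

#' @export
print.tat_comparison <- function(x, ...) {
  cat("TaT comparison (group 1 minus group 2)\n")
  cat("  group 1: "); print(x$summary_cm)
  cat("  group 2: "); print(x$summary_dp)
  cat(sprintf("  mean difference   %.2f days\n", x$mean_difference))
  cat(sprintf("  median difference %.2f days\n", x$median_difference))
  if (x$degenerate) {
    cat("  all values identical in both groups: no evidence of a difference\n")
  } else {
    cat(sprintf("  Welch t = %.3f, p = %.3g\n", x$t_statistic, x$t_pvalue))
    cat(sprintf("  Mann-Whitney U = %g, p = %.3g\n", x$u_statistic, x$u_pvalue))
  }
  invisible(x)
}

#' Rank correlation between slide-count category and TaT
#'
#' Slide categories are mapped to ordinals 1-4 and Spearman's rho with
#' tie-corrected midranks is computed against TaT.  A constant TaT or a
#' single represented category makes the coefficient undefined; the result
#' is then flagged rather than an error.
#'
#' @param cases validated case data.frame (>= 3 records).
#' @return list with `rho`, `p_value` and `defined`.
#' @export
slide_association <- function(cases) {
  stopifnot(nrow(cases) >= 3L)
  ord <- as.integer(factor(cases$slide_category, levels = SLIDE_CATEGORIES))
  tat <- tat_days(cases)
  if (length(unique(ord)) < 2L || length(unique(tat)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(ord, tat, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, defined = TRUE)
}

#' Generic 2 x k contingency comparison of a categorical variable
#'
#' Utility comparing the composition of a categorical variable between the
#' two methodology groups, via chi-square or Fisher's exact test.
#'
#' @param cases validated case data.frame.
#' @param variable column name of the categorical variable.
#' @param test `"chisq"` or `"fisher"`.
#' @return list with the contingency `table` and the test `p_value`.
#' @export
compare_composition <- function(cases, variable, test = c("chisq", "fisher")) {
  test <- match.arg(test)
  tab <- table(cases$methodology, cases[[variable]])
  p <- if (test == "chisq") stats::chisq.test(tab)$p.value
       else stats::fisher.test(tab, simulate.p.value = (min(dim(tab)) > 2))$p.value
  list(table = tab, p_value = p)
}
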