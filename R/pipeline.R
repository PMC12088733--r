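# End-to-end pipeline: generate/read -> validate -> TaT analysis ->
# backlog -> workload -> cost, exporting the tables behind every figure
# of the analysis as plain CSV/JSON.

#' Pipeline configuration
#'
#' Exactly one input source per year: either a synthetic [cohort_spec()]
#' (covering both years) or a pair of case CSVs.
#'
#' @param out_dir output directory (created if needed).
#' @param spec synthetic [cohort_spec()]; ignored when both CSVs are given.
#' @param cases_cm_csv,cases_dp_csv optional case CSV paths, one per year.
#' @param annual_working_days,diagnostic_time_fraction capacity settings
#'   shared by both pathologists; the annual caseload per pathologist is
#'   taken from the data.
#' @param inventory equipment data.frame (default [default_inventory()]).
#' @param cost a [cost_params()].
#' @param seed overrides the spec's seed when not `NULL`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, spec = cohort_spec(),
                            cases_cm_csv = NULL, cases_dp_csv = NULL,
                            annual_working_days = 220L,
                            diagnostic_time_fraction = 0.60,
                            inventory = default_inventory(),
                            cost = cost_params(), seed = NULL) {
  use_csv <- !is.null(cases_cm_csv) || !is.null(cases_dp_csv)
  if (use_csv && (is.null(cases_cm_csv) || is.null(cases_dp_csv))) {
    stop("provide case CSVs for both years, or neither")
  }
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, spec = spec,
                 cases_cm_csv = cases_cm_csv, cases_dp_csv = cases_dp_csv,
                 annual_working_days = as.integer(annual_working_days),
                 diagnostic_time_fraction = diagnostic_time_fraction,
                 inventory = inventory, cost = cost),
            class = "pipeline_config")
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  path
}

#' Run the full efficiency-comparison pipeline
#'
#' Executes every stage and writes to `config$out_dir`:
#' \describe{
#'   \item{cases.csv}{the analyzed case records (synthetic runs only).}
#'   \item{tat_summary.csv}{TaT summaries overall and per stratum
#'     (pathologist, slide category, area) within each methodology.}
#'   \item{tat_comparison.json}{the two-group comparison (mean/median
#'     differences, Welch t, Mann--Whitney U) overall and per pathologist,
#'     plus the slide-count rank association.}
#'   \item{pending_cm.csv / pending_dp.csv}{daily pending census, long
#'     format.}
#'   \item{backlog_summary.csv}{per-pathologist means and peaks for both
#'     years, with the reduction.}
#'   \item{workload_calendar_cm.csv / _dp.csv}{daily workload index.}
#'   \item{workload_reduction.csv}{per-month and overall percent
#'     reduction.}
#'   \item{cost_report.json}{both scenarios in both modes, plus the cost
#'     per workload point freed.}
#'   \item{manifest.json}{seed, config hash, package and R versions.}
#' }
#' Any stage failure removes the partial outputs and signals an error
#' tagged with the stage name.  Re-running with the same config (hence
#' same manifest hash) reproduces all outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the analyzed cases and every stage
#'   result.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(...) if (!quiet) message(...)
  emit <- function(path) { written <<- c(written, path); path }
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }
  out <- function(f) file.path(config$out_dir, f)

  # -- input ----------------------------------------------------------
  cases <- stage("input", {
    if (!is.null(config$cases_cm_csv)) {
      cm <- read_cases(config$cases_cm_csv)
      dp <- read_cases(config$cases_dp_csv)
      note(sprintf("input: %d + %d cases read, %d + %d excluded",
                   cm$report$n_analyzed, dp$report$n_analyzed,
                   cm$report$n_excluded_missing, dp$report$n_excluded_missing))
      rbind(cm$cases, dp$cases)
    } else {
      x <- generate_cohort(config$spec)
      write_cases(x, emit(out("cases.csv")))
      note(sprintf("input: %d synthetic cases generated (seed %d)",
                   nrow(x), config$spec$seed))
      x
    }
  })
  year_cm <- as.integer(format(min(cases$receipt_date[cases$methodology == "CM"]), "%Y"))
  year_dp <- as.integer(format(min(cases$receipt_date[cases$methodology == "DP"]), "%Y"))

  # -- TaT analysis ---------------------------------------------------
  tat_res <- stage("tat_analysis", {
    tat <- tat_days(cases)
    rows <- list(data.frame(methodology = "all", stratum_by = "none",
                            tat_summary_table(summarize_tat(cases))))
    for (m in METHODOLOGIES) {
      sub <- cases[cases$methodology == m, ]
      rows[[length(rows) + 1L]] <- data.frame(methodology = m, stratum_by = "none",
                                              tat_summary_table(summarize_tat(sub)))
      for (by in c("pathologist", "slide_category", "area")) {
        rows[[length(rows) + 1L]] <- data.frame(methodology = m, stratum_by = by,
                                                tat_summary_table(summarize_tat(sub, by)))
      }
    }
    summary_tab <- do.call(rbind, rows)
    utils::write.csv(summary_tab, emit(out("tat_summary.csv")), row.names = FALSE)

    cmp_all <- compare_tat(tat[cases$methodology == "CM"],
                           tat[cases$methodology == "DP"])
    cmp_path <- lapply(stats::setNames(nm = PATHOLOGISTS), function(p) {
      sub <- cases$pathologist == p
      compare_tat(tat[sub & cases$methodology == "CM"],
                  tat[sub & cases$methodology == "DP"])
    })
    assoc <- slide_association(cases)
    .write_json(list(
      overall = unclass(cmp_all),
      by_pathologist = lapply(cmp_path, unclass),
      slide_association = assoc
    ), emit(out("tat_comparison.json")))
    note(sprintf("tat: mean difference %.2f days (Welch p = %.2g)",
                 cmp_all$mean_difference, cmp_all$t_pvalue))
    list(summary = summary_tab, comparison = cmp_all,
         by_pathologist = cmp_path, slide_association = assoc)
  })

  # -- backlog --------------------------------------------------------
  backlog_res <- stage("backlog", {
    pm_cm <- pending_matrix(cases[cases$methodology == "CM", ], year_cm)
    pm_dp <- pending_matrix(cases[cases$methodology == "DP", ], year_dp)
    utils::write.csv(pending_long(pm_cm), emit(out("pending_cm.csv")), row.names = FALSE)
    utils::write.csv(pending_long(pm_dp), emit(out("pending_dp.csv")), row.names = FALSE)
    s_cm <- summarize_backlog(pm_cm)
    s_dp <- summarize_backlog(pm_dp)
    red <- compare_backlogs(s_cm, s_dp)
    tab <- rbind(data.frame(methodology = "CM", as.data.frame(s_cm)),
                 data.frame(methodology = "DP", as.data.frame(s_dp)))
    tab$peak_date <- format(tab$peak_date, "%Y-%m-%d")
    utils::write.csv(tab, emit(out("backlog_summary.csv")), row.names = FALSE)
    note(sprintf("backlog: mean daily pending reduced by %.2f cases on average",
                 red$average))
    list(matrix_cm = pm_cm, matrix_dp = pm_dp, summary_cm = s_cm,
         summary_dp = s_dp, reduction = red)
  })

  # -- workload -------------------------------------------------------
  workload_res <- stage("workload", {
    caps <- function(m) {
      sub <- cases[cases$methodology == m, ]
      lapply(stats::setNames(nm = PATHOLOGISTS), function(p) {
        capacity_params(sum(sub$pathologist == p),
                        config$annual_working_days,
                        config$diagnostic_time_fraction)
      })
    }
    cal_cm <- workload_calendar(backlog_res$matrix_cm, caps("CM"))
    cal_dp <- workload_calendar(backlog_res$matrix_dp, caps("DP"))
    utils::write.csv(cal_cm, emit(out("workload_calendar_cm.csv")), row.names = FALSE)
    utils::write.csv(cal_dp, emit(out("workload_calendar_dp.csv")), row.names = FALSE)
    red <- workload_reduction(cal_cm, cal_dp)
    monthly <- red$monthly
    monthly$period <- sprintf("month %02d", monthly$month)
    utils::write.csv(
      rbind(monthly[, c("period", "mean_index_a", "mean_index_b", "reduction_pct")],
            data.frame(period = "year", mean_index_a = red$mean_index_a,
                       mean_index_b = red$mean_index_b,
                       reduction_pct = red$reduction_pct)),
      emit(out("workload_reduction.csv")), row.names = FALSE)
    note(sprintf("workload: %.1f%% annual reduction in workload index",
                 red$reduction_pct))
    list(calendar_cm = cal_cm, calendar_dp = cal_dp, reduction = red)
  })

  # -- cost -----------------------------------------------------------
  cost_res <- stage("cost", {
    res <- list()
    for (sc in c("replacement", "new-laboratory")) {
      for (md in c("acquisition", "depreciated")) {
        res[[paste(sc, md, sep = ".")]] <-
          unclass(scenario_cost(config$inventory, sc, config$cost, md))
      }
    }
    wred <- workload_res$reduction$reduction_pct
    res$cost_per_workload_point <- if (!is.na(wred) && wred > 0) {
      cost_per_workload_point(res$`replacement.acquisition`$annual_overrun, wred)
    } else NA_real_
    .write_json(res, emit(out("cost_report.json")))
    note(sprintf("cost: replacement over-run %s EUR/year",
                 format(res$`replacement.acquisition`$annual_overrun,
                        big.mark = ",")))
    res
  })

  # -- manifest -------------------------------------------------------
  stage("manifest", {
    cfg_json <- jsonlite::toJSON(list(
      spec = unclass(config$spec),
      capacity = list(working_days = config$annual_working_days,
                      fraction = config$diagnostic_time_fraction),
      cost = unclass(config$cost),
      inventory = config$inventory
    ), auto_unbox = TRUE, digits = NA, force = TRUE)
    tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
    hash <- unname(tools::md5sum(tmp)); unlink(tmp)
    .write_json(list(
      seed = config$spec$seed,
      config_md5 = hash,
      n_cases = nrow(cases),
      package_version = as.character(utils::packageVersion("pathflow")),
      r_version = paste(R.version$major, R.version$minor, sep = ".")
    ), emit(out("manifest.json")))
  })

  invisible(list(cases = cases, tat = tat_res, backlog = backlog_res,
                 workload = workload_res, cost = cost_res,
                 files = written))
}
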