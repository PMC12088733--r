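#' @keywords internal
"_PACKAGE"

# Canonical category labels used throughout the package.  Labels are ASCII so
# that CSV round-trips are encoding-proof.
PATHOLOGISTS <- c("A", "B")
METHODOLOGIES <- c("CM", "DP")
SLIDE_CATEGORIES <- c("1", "2", "3-4", ">=5")
AREA_CATEGORIES <- c(
  "head-neck-endocrine", "dermatopathology", "complex-digestive",
  "gynaecology-uropathology", "neuropathology", "other"
)
CASE_COLUMNS <- c(
  "case_id", "receipt_date", "report_date", "pathologist",
  "methodology", "slide_category", "area"
)

#' Bin raw slide counts into the four analysis categories
#'
#' Slide counts are analysed in four bins: 1, 2, 3-4 and >=5 slides.  This
#' helper maps a raw integer count to its bin label.
#'
#' @param n integer vector of slide counts (>= 1).
#' @return character vector of category labels.
#' @examples
#' slide_bin(c(1, 2, 3, 4, 5, 12))
#' @export
slide_bin <- function(n) {
  stopifnot(is.numeric(n), all(is.na(n) | n >= 1))
  out <- rep(NA_character_, length(n))
  out[n == 1] <- "1"
  out[n == 2] <- "2"
  out[n == 3 | n == 4] <- "3-4"
  out[n >= 5] <- ">=5"
  out
}

#' Validate a case-record table
#'
#' Applies the completeness filter that defines the analysis set: rows with
#' any missing required field, an unknown category label, or a report date
#' earlier than the receipt date are excluded and itemized; valid rows are
#' returned with canonical column order and factor levels.  Validation never
#' aborts on a bad row -- exclusion mirrors how incomplete cases are dropped
#' from a retrospective analysis set.
#'
#' A methodology label that contradicts the receipt year of the study design
#' (CM in the conventional-microscopy year, DP in the digital year) is flagged
#' as a warning in the report but the row is kept: the label, not the year,
#' is authoritative.
#'
#' @param df data.frame with the columns listed in [read_cases()].
#' @param year_cm,year_dp calendar years against which methodology labels are
#'   cross-checked; use `NULL` to skip the check.
#' @return list with elements `cases` (validated data.frame) and `report`
#'   (a `validation_report` object).
#' @export
validate_cases <- function(df, year_cm = 2021L, year_dp = 2022L) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(CASE_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("case table lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  n_input <- nrow(df)
  reasons <- character(n_input)

  bad <- function(cond, why) {
    cond <- !is.na(cond) & cond
    reasons[cond & reasons == ""] <<- why
  }

  for (col in CASE_COLUMNS) {
    miss <- is.na(df[[col]]) | (is.character(df[[col]]) & !nzchar(trimws(as.character(df[[col]]))))
    bad(miss, paste0("missing ", col))
  }
  bad(!(df$pathologist %in% PATHOLOGISTS) & reasons == "", "unknown pathologist label")
  bad(!(df$methodology %in% METHODOLOGIES) & reasons == "", "unknown methodology label")
  bad(!(df$slide_category %in% SLIDE_CATEGORIES) & reasons == "", "unknown slide category")
  bad(!(df$area %in% AREA_CATEGORIES) & reasons == "", "unknown area label")
  both <- !is.na(df$receipt_date) & !is.na(df$report_date)
  bad(both & df$report_date < df$receipt_date, "negative interval")

  keep <- reasons == ""
  cases <- df[keep, CASE_COLUMNS, drop = FALSE]
  rownames(cases) <- NULL
  cases$receipt_date <- as.Date(cases$receipt_date)
  cases$report_date <- as.Date(cases$report_date)
  cases$pathologist <- factor(cases$pathologist, levels = PATHOLOGISTS)
  cases$methodology <- factor(cases$methodology, levels = METHODOLOGIES)
  cases$slide_category <- factor(cases$slide_category, levels = SLIDE_CATEGORIES)
  cases$area <- factor(cases$area, levels = AREA_CATEGORIES)

  warnings <- character(0)
  if (!is.null(year_cm) && !is.null(year_dp) && nrow(cases) > 0L) {
    yr <- as.integer(format(cases$receipt_date, "%Y"))
    expected <- ifelse(yr == year_cm, "CM", ifelse(yr == year_dp, "DP", NA))
    mism <- !is.na(expected) & as.character(cases$methodology) != expected
    if (any(mism)) {
      warnings <- sprintf(
        "case %s: methodology %s but receipt year %d",
        cases$case_id[mism], cases$methodology[mism], yr[mism]
      )
    }
  }

  excl <- data.frame(
    case_id = as.character(df$case_id[!keep]),
    reason = reasons[!keep],
    stringsAsFactors = FALSE
  )
  report <- structure(
    list(
      n_input = n_input,
      n_excluded_missing = sum(!keep),
      n_analyzed = sum(keep),
      exclusion_reasons = excl,
      warnings = warnings
    ),
    class = "validation_report"
  )
  list(cases = cases, report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Case validation report\n")
  cat(sprintf("  recorded cases : %d\n", x$n_input))
  cat(sprintf("  excluded       : %d\n", x$n_excluded_missing))
  cat(sprintf("  analyzed       : %d\n", x$n_analyzed))
  if (nrow(x$exclusion_reasons) > 0L) {
    tab <- table(x$exclusion_reasons$reason)
    for (r in names(tab)) cat(sprintf("    %-28s %d\n", r, tab[[r]]))
  }
  if (length(x$warnings) > 0L) {
    cat(sprintf("  warnings       : %d (methodology/year mismatches)\n", length(x$warnings)))
  }
  invisible(x)
}

#' Read and validate a case-record CSV
#'
#' Reads one row per biopsy case (identifier, receipt and report dates,
#' pathologist, methodology, slide category, case area), parses dates
#' strictly against `date_format`, and applies [validate_cases()].  Rows that
#' fail to parse or are incomplete are excluded and itemized, never fatal.
#'
#' @param path path to a CSV file with columns `case_id`, `receipt_date`,
#'   `report_date`, `pathologist`, `methodology`, `slide_category`, `area`
#'   (renameable via `col_map`).
#' @param date_format a `strptime` format string for the two date columns;
#'   stored dates are always ISO-8601.
#' @param col_map optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(case_id = "id", receipt_date = "in")`.
#' @param year_cm,year_dp passed to [validate_cases()].
#' @return list with `cases` (validated data.frame of complete records) and
#'   `report` (a `validation_report`).
#' @seealso [write_cases()]
#' @export
read_cases <- function(path, date_format = "%Y-%m-%d", col_map = NULL,
                       year_cm = 2021L, year_dp = 2022L) {
  if (!file.exists(path)) stop("case file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0L && ncol(raw) == 0L) stop("empty case file: ", path)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  missing_cols <- setdiff(CASE_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("case file lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  raw$receipt_date <- as.Date(raw$receipt_date, format = date_format)
  raw$report_date <- as.Date(raw$report_date, format = date_format)
  validate_cases(raw, year_cm = year_cm, year_dp = year_dp)
}

#' Write case records to CSV
#'
#' Writes the canonical column order with ISO-8601 dates so that
#' `read_cases(write_cases(x))` is the identity on valid records.
#'
#' @param cases validated case data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  stopifnot(is.data.frame(cases))
  out <- cases[, CASE_COLUMNS, drop = FALSE]
  out$receipt_date <- format(as.Date(out$receipt_date), "%Y-%m-%d")
  out$report_date <- format(as.Date(out$report_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an equipment-inventory CSV
#'
#' @param path CSV with columns `item`, `workflow` (CM|DP),
#'   `acquisition_year`, `unit_cost_eur`, `quantity`, `one_off` (true|false).
#' @return data.frame of equipment items.
#' @export
read_equipment <- function(path) {
  if (!file.exists(path)) stop("equipment file not found: ", path)
  inv <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("item", "workflow", "acquisition_year", "unit_cost_eur",
                "quantity", "one_off")
  missing_cols <- setdiff(required, names(inv))
  if (length(missing_cols) > 0L) {
    stop("equipment file lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(inv$workflow %in% METHODOLOGIES),
            all(inv$unit_cost_eur >= 0), all(inv$quantity >= 1))
  inv$one_off <- as.logical(inv$one_off)
  inv
}
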