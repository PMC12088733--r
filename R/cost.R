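# Exploratory equipment cost model: scenario totals, annualized over-runs,
# depreciation-and-discounting schedule, and cost per workload point.

# Half-up rounding to whole euros (base round() is round-half-even).
round_eur <- function(x) {
  s <- ifelse(x < 0, -1, 1)
  s * floor(abs(x) + 0.5)
}

#' Cost-model parameters
#'
#' @param horizon_start,horizon_end analysis period in years, both
#'   included (defaults 2021-2025).
#' @param depreciation_years equipment service life over which purchase
#'   prices are spread (default 6).
#' @param discount_rate annual discount rate applied to future costs
#'   (default 0.03).
#' @param discount_from_year first year whose costs are discounted
#'   (default 2022: base-year costs are carried at face value).
#' @param base_year present-value reference year (default 2021).
#' @return object of class `cost_params`.
#' @export
cost_params <- function(horizon_start = 2021L, horizon_end = 2025L,
                        depreciation_years = 6L, discount_rate = 0.03,
                        discount_from_year = 2022L, base_year = 2021L) {
  stopifnot(horizon_end >= horizon_start, depreciation_years > 0,
            discount_rate >= 0, discount_rate < 1)
  structure(list(horizon_start = as.integer(horizon_start),
                 horizon_end = as.integer(horizon_end),
                 depreciation_years = as.integer(depreciation_years),
                 discount_rate = discount_rate,
                 discount_from_year = as.integer(discount_from_year),
                 base_year = as.integer(base_year)),
            class = "cost_params")
}

#' Default equipment inventory
#'
#' A synthetic inventory reproducing the two workflows' equipment totals:
#' eight binocular LED microscopes for the conventional workflow (six
#' acquired before the analysis horizon and already amortized, two
#' purchased within it), and the digital workflow's scanner bundle
#' (scanner, viewing software, 10 TB server, image-analysis algorithms)
#' plus nine diagnostic workstations, all acquired in the base year.  Item
#' prices are plausible splits of the workflow totals, not a published
#' parts list; override with [read_equipment()] for a real inventory.
#'
#' @return equipment data.frame (see [read_equipment()] for columns).
#' @export
default_inventory <- function() {
  data.frame(
    item = c("binocular LED microscope with battery (amortized stock)",
             "binocular LED microscope with battery (new purchase)",
             "WSI scanner bundle (scanner, software, 10 TB server, algorithms)",
             "diagnostic workstation (computer + monitor)"),
    workflow = c("CM", "CM", "DP", "DP"),
    acquisition_year = c(2015L, 2021L, 2021L, 2021L),
    unit_cost_eur = c(1875, 1875, 141888, 2500),
    quantity = c(6L, 2L, 1L, 9L),
    one_off = c(TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Depreciated, discounted cost of one inventory row over the horizon.
.item_discounted_cost <- function(unit_cost, quantity, acq_year, one_off, p) {
  total <- unit_cost * quantity
  disc <- function(y) {
    if (y < p$discount_from_year) 1
    else (1 + p$discount_rate)^(-(y - p$base_year))
  }
  if (one_off) {
    # Full cost incurred at acquisition; base-year one-offs undiscounted.
    if (acq_year > p$horizon_end) return(0)
    y <- max(acq_year, p$horizon_start)
    return(total * disc(y))
  }
  years <- seq(max(acq_year, p$horizon_start),
               min(acq_year + p$depreciation_years - 1L, p$horizon_end))
  if (length(years) == 0L || years[1] > years[length(years)]) return(0)
  sum(vapply(years, function(y) total / p$depreciation_years * disc(y),
             numeric(1)))
}

#' Scenario cost of the two workflows' equipment
#'
#' Two scenarios: in the *replacement* scenario the conventional workflow
#' is charged only for microscopes newly purchased within the analysis
#' horizon (the amortized stock is free); in the *new-laboratory* scenario
#' every conventional item is charged as a base-year purchase.  The digital
#' workflow is charged in full in both.  Two modes: *acquisition* sums
#' purchase prices of in-horizon items; *depreciated* spreads non-one-off
#' purchases over the depreciation life and discounts future-year costs
#' (one-off items are charged at acquisition, undiscounted in the base
#' year).
#'
#' @param inventory equipment data.frame ([read_equipment()] /
#'   [default_inventory()]); may be empty (zero-cost result).
#' @param scenario `"replacement"` or `"new-laboratory"`.
#' @param params a [cost_params()].
#' @param mode `"acquisition"` or `"depreciated"`.
#' @return object of class `scenario_result` with euro totals per workflow,
#'   their difference (DP minus CM) and the annual over-run (difference
#'   divided by the horizon length, rounded half-up to whole euros).
#' @examples
#' scenario_cost(default_inventory(), "replacement")
#' @export
scenario_cost <- function(inventory, scenario = c("replacement", "new-laboratory"),
                          params = cost_params(),
                          mode = c("acquisition", "depreciated")) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  stopifnot(inherits(params, "cost_params"))
  inv <- inventory
  if (nrow(inv) > 0L && scenario == "replacement") {
    keep <- inv$workflow == "DP" |
      (inv$acquisition_year >= params$horizon_start &
         inv$acquisition_year <= params$horizon_end)
    inv <- inv[keep, , drop = FALSE]
  }
  if (nrow(inv) > 0L && scenario == "new-laboratory") {
    inv$acquisition_year[inv$workflow == "CM"] <- params$base_year
  }
  wf_cost <- function(wf) {
    rows <- inv[inv$workflow == wf, , drop = FALSE]
    if (nrow(rows) == 0L) return(0)
    if (mode == "acquisition") {
      in_h <- rows$acquisition_year <= params$horizon_end
      return(sum(rows$unit_cost_eur[in_h] * rows$quantity[in_h]))
    }
    sum(vapply(seq_len(nrow(rows)), function(i) {
      .item_discounted_cost(rows$unit_cost_eur[i], rows$quantity[i],
                            rows$acquisition_year[i], rows$one_off[i], params)
    }, numeric(1)))
  }
  cost_cm <- wf_cost("CM")
  cost_dp <- wf_cost("DP")
  horizon_years <- params$horizon_end - params$horizon_start + 1L
  structure(list(
    scenario = scenario, mode = mode,
    cost_cm = cost_cm, cost_dp = cost_dp,
    difference = cost_dp - cost_cm,
    annual_overrun = round_eur((cost_dp - cost_cm) / horizon_years),
    horizon_years = horizon_years
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Equipment cost, %s scenario (%s mode)\n", x$scenario, x$mode))
  cat(sprintf("  CM workflow : %s EUR\n", format(x$cost_cm, big.mark = ",")))
  cat(sprintf("  DP workflow : %s EUR\n", format(x$cost_dp, big.mark = ",")))
  cat(sprintf("  difference  : %s EUR over %d years (%s EUR/year over-run)\n",
              format(x$difference, big.mark = ","), x$horizon_years,
              format(x$annual_overrun, big.mark = ",")))
  invisible(x)
}

#' Cost of freeing one percentage point of pathologist workload
#'
#' Annual equipment over-run divided by the percent workload reduction the
#' digital workflow achieves, rounded half-up to whole euros.
#'
#' @param annual_overrun euros per year (from [scenario_cost()]).
#' @param workload_reduction_pct percent reduction (> 0), e.g. from
#'   [workload_reduction()].
#' @return euros per percentage point of workload freed.
#' @export
cost_per_workload_point <- function(annual_overrun, workload_reduction_pct) {
  if (workload_reduction_pct <= 0) {
    stop("workload reduction must be positive to cost a freed point")
  }
  round_eur(annual_overrun / workload_reduction_pct)
}
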