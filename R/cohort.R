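# Synthetic two-year case-flow generator.
#
# The generator emulates a biopsy case flow across two calendar years, one
# per diagnostic workflow (conventional microscopy, then digital pathology),
# with monthly seasonality, a two-pathologist split, categorical slide-count
# and case-area composition, and integer-day turnaround times (TaT) drawn
# from a distribution calibrated to match a set of printed summary targets
# (mean, SD, median, quartiles, range) analytically, not by sampling.

#' Turnaround-time distribution targets
#'
#' Bundle of the summary statistics a calibrated TaT distribution must
#' reproduce.  TaT is integer-valued in calendar days with minimum 1
#' (same-day sign-out counts as one day).
#'
#' @param mean,sd target mean and standard deviation, in days.
#' @param median,q25,q75 target median and quartiles, in days.
#' @param min,max support bounds in days; `min` is fixed at 1 by the TaT
#'   convention, `max` truncates the distribution.
#' @return object of class `tat_target`.
#' @export
tat_target <- function(mean, sd, median, q25, q75, min = 1, max) {
  stopifnot(sd > 0, min <= q25, q25 <= median, median <= q75, q75 <= max)
  structure(list(mean = mean, sd = sd, median = median, q25 = q25,
                 q75 = q75, min = min, max = max),
            class = "tat_target")
}

# Discretized two-component gamma mixture on integer days 1..max:
# pmf(k) = [F(k) - F(k-1)] / F(max), F the mixture CDF.
.mixture_pmf <- function(par, max_day) {
  w <- stats::plogis(par[1])
  k1 <- exp(par[2]); th1 <- exp(par[3])
  k2 <- exp(par[4]); th2 <- exp(par[5])
  Fm <- function(x) {
    w * stats::pgamma(x, shape = k1, scale = th1) +
      (1 - w) * stats::pgamma(x, shape = k2, scale = th2)
  }
  Fk <- Fm(0:max_day)
  pmf <- diff(Fk)
  tot <- Fk[max_day + 1L]
  if (tot <= 0 || any(!is.finite(pmf))) return(NULL)
  pmf / tot
}

# Interpolated quantile of a discrete distribution on support 1..max: the
# CDF is treated as piecewise linear between consecutive integer knots
# (anchored at F(0) = 0), the common linear-interpolation convention.
.pmf_quantile <- function(pmf, p) {
  Fk <- c(0, cumsum(pmf))
  vapply(p, function(pp) {
    k <- which(Fk >= pp - 1e-12)[1] - 1L   # smallest k with F(k) >= p
    if (k == 0L) return(0)
    lo <- Fk[k]; hi <- Fk[k + 1L]
    (k - 1L) + (pp - lo) / (hi - lo)
  }, numeric(1))
}

.pmf_summary <- function(pmf) {
  support <- seq_along(pmf)
  m <- sum(support * pmf)
  v <- sum((support - m)^2 * pmf)
  q <- .pmf_quantile(pmf, c(0.25, 0.5, 0.75))
  list(mean = m, sd = sqrt(v), median = q[2], q25 = q[1], q75 = q[3])
}

#' Calibrate a discrete TaT distribution to summary targets
#'
#' Fits a discretized two-component gamma mixture on integer days
#' `1..target$max` whose analytically computed mean, SD, median and
#' quartiles match the target.  A single two-parameter family cannot match
#' five summaries simultaneously; the mixture's five free parameters can.
#' Calibration minimizes a sum of squared discrepancies standardized by the
#' acceptance tolerances (0.1 day on the mean, 0.2 on the SD, 1 day on
#' median and quartiles) by Nelder--Mead from a fixed grid of starting
#' points, so the fit is deterministic.
#'
#' @param target a [tat_target()].
#' @param tol named numeric vector of acceptance tolerances; calibration
#'   fails if any achieved discrepancy exceeds its tolerance.
#' @return object of class `tat_distribution`: the probability mass function
#'   over `1..max`, the achieved summaries and their discrepancies.
#' @examples
#' d <- calibrate_tat_distribution(tat_target(6.86, 5.10, 5, 3, 9, 1, 44))
#' d$summary
#' @export
calibrate_tat_distribution <- function(target,
                                       tol = c(mean = 0.1, sd = 0.2,
                                               median = 1, q25 = 1, q75 = 1)) {
  stopifnot(inherits(target, "tat_target"))
  max_day <- as.integer(target$max)

  # The fit is deterministic in the target, so cache it per session.
  key <- paste(unlist(target), collapse = "|")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])

  objective <- function(par) {
    pmf <- .mixture_pmf(par, max_day)
    if (is.null(pmf)) return(1e8)
    s <- .pmf_summary(pmf)
    ((s$mean - target$mean) / 0.05)^2 +
      ((s$sd - target$sd) / 0.10)^2 +
      ((s$median - target$median) / 0.50)^2 +
      ((s$q25 - target$q25) / 0.50)^2 +
      ((s$q75 - target$q75) / 0.50)^2
  }

  # Moment-matched single gamma as the anchor; starts spread the two
  # components below and above it with varying mixture weights.
  k0 <- (target$mean / target$sd)^2
  th0 <- target$sd^2 / target$mean
  starts <- list()
  for (w in c(0.35, 0.5, 0.65)) {
    for (spread in c(1.6, 2.5)) {
      starts[[length(starts) + 1L]] <- c(
        stats::qlogis(w),
        log(k0), log(th0 / spread),
        log(k0), log(th0 * spread)
      )
    }
  }

  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  pmf <- .mixture_pmf(best$par, max_day)
  s <- .pmf_summary(pmf)
  disc <- c(mean = s$mean - target$mean, sd = s$sd - target$sd,
            median = s$median - target$median, q25 = s$q25 - target$q25,
            q75 = s$q75 - target$q75)
  ok <- abs(disc) <= tol[names(disc)]
  if (!all(ok)) {
    stop(errorCondition(
      paste0("TaT calibration failed; worst discrepancy ",
             names(disc)[which.max(abs(disc) / tol[names(disc)])],
             " = ", signif(disc[which.max(abs(disc) / tol[names(disc)])], 3)),
      discrepancy = disc,
      class = c("pathflow_calibration_error", "error", "condition")
    ))
  }
  res <- structure(list(
    family = "discretized-gamma-mixture",
    parameters = c(weight = stats::plogis(best$par[1]),
                   shape1 = exp(best$par[2]), scale1 = exp(best$par[3]),
                   shape2 = exp(best$par[4]), scale2 = exp(best$par[5])),
    support = seq_len(max_day),
    pmf = pmf,
    summary = s,
    discrepancy = disc,
    target = target
  ), class = "tat_distribution")
  .calibration_cache[[key]] <- res
  res
}

.calibration_cache <- new.env(parent = emptyenv())

#' @export
print.tat_distribution <- function(x, ...) {
  cat(sprintf("Calibrated TaT distribution (%s) on 1..%d days\n",
              x$family, max(x$support)))
  s <- x$summary; t <- x$target
  cat(sprintf("  mean %.3f (target %.2f)  sd %.3f (target %.2f)\n",
              s$mean, t$mean, s$sd, t$sd))
  cat(sprintf("  q25/median/q75 %.2f/%.2f/%.2f (target %g/%g/%g)\n",
              s$q25, s$median, s$q75, t$q25, t$median, t$q75))
  invisible(x)
}

#' Specification of a synthetic two-year cohort
#'
#' Defaults emulate a two-year biopsy case flow: 5,836 conventional-
#' microscopy (CM) cases in 2021 and 6,086 digital-pathology (DP) cases in
#' 2022; uniform monthly volume except a summer dip (July and August at 60%
#' of the uniform share); a 50/50 split between two pathologists; the
#' observed slide-count category frequencies (36.74% / 21.56% / 22.48% /
#' 19.22% for 1 / 2 / 3-4 / >=5 slides); and group TaT summary targets of
#' mean 10.58 (SD 7.10), median 9, quartiles 6 and 15, max 55 days for CM
#' versus mean 6.86 (SD 5.10), median 5, quartiles 3 and 9, max 44 for DP.
#'
#' @param n_cm,n_dp group sizes.
#' @param year_cm,year_dp receipt years of the two groups.
#' @param monthly_weights 12 non-negative weights summing to 1.
#' @param pathologist_split probability a case is assigned to pathologist A.
#' @param slide_probs probabilities over the four slide categories.
#' @param area_probs probabilities over the six case areas.
#' @param tat_target_cm,tat_target_dp [tat_target()] objects per group.
#' @param seed integer RNG seed; the cohort is fully reproducible from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cm = 5836L, n_dp = 6086L,
                        year_cm = 2021L, year_dp = 2022L,
                        monthly_weights = default_monthly_weights(),
                        pathologist_split = 0.5,
                        slide_probs = c(`1` = 0.3674, `2` = 0.2156,
                                        `3-4` = 0.2248, `>=5` = 0.1922),
                        area_probs = c(`head-neck-endocrine` = 0.18,
                                       dermatopathology = 0.27,
                                       `complex-digestive` = 0.22,
                                       `gynaecology-uropathology` = 0.18,
                                       neuropathology = 0.03,
                                       other = 0.12),
                        tat_target_cm = tat_target(10.58, 7.10, 9, 6, 15, 1, 55),
                        tat_target_dp = tat_target(6.86, 5.10, 5, 3, 9, 1, 44),
                        seed = 20210101L) {
  stopifnot(n_cm > 0, n_dp > 0,
            length(monthly_weights) == 12L, all(monthly_weights >= 0),
            abs(sum(monthly_weights) - 1) < 1e-9,
            length(slide_probs) == 4L, abs(sum(slide_probs) - 1) < 1e-9,
            length(area_probs) == 6L, abs(sum(area_probs) - 1) < 1e-9,
            pathologist_split >= 0, pathologist_split <= 1)
  structure(list(
    n_cm = as.integer(n_cm), n_dp = as.integer(n_dp),
    year_cm = as.integer(year_cm), year_dp = as.integer(year_dp),
    monthly_weights = monthly_weights,
    pathologist_split = pathologist_split,
    slide_probs = slide_probs, area_probs = area_probs,
    tat_target_cm = tat_target_cm, tat_target_dp = tat_target_dp,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default monthly seasonality weights
#'
#' Uniform across months except July and August at 60% of the uniform
#' share, renormalized -- the characteristic summer dip of a hospital
#' pathology department's case volume.
#'
#' @return numeric vector of 12 weights summing to 1.
#' @export
default_monthly_weights <- function() {
  w <- rep(1, 12)
  w[7:8] <- 0.6
  w / sum(w)
}

.days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt <- seq(first, by = "1 month", length.out = 2)[2]
  as.integer(nxt - first)
}

.generate_group <- function(n, year, methodology, dist, spec) {
  month <- sample.int(12L, n, replace = TRUE, prob = spec$monthly_weights)
  dim <- vapply(1:12, .days_in_month, integer(1), year = year)
  day <- 1L + as.integer(floor(stats::runif(n) * dim[month]))
  receipt <- as.Date(sprintf("%d-%02d-%02d", year, month, day))
  tat <- sample(dist$support, n, replace = TRUE, prob = dist$pmf)
  data.frame(
    case_id = sprintf("%s-%d-%06d", methodology, year, seq_len(n)),
    receipt_date = receipt,
    report_date = receipt + (tat - 1L),
    pathologist = ifelse(stats::runif(n) < spec$pathologist_split, "A", "B"),
    methodology = methodology,
    slide_category = sample(SLIDE_CATEGORIES, n, replace = TRUE,
                            prob = spec$slide_probs),
    area = sample(AREA_CATEGORIES, n, replace = TRUE, prob = spec$area_probs),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic two-year cohort
#'
#' Draws `n_cm + n_dp` case records.  Receipt dates are drawn by monthly
#' weight, then uniformly within the month; the TaT is drawn from the
#' group's calibrated distribution and `report_date = receipt_date +
#' (TaT - 1)` days, so same-day issuance corresponds to TaT = 1.
#' Pathologist, slide category and area are drawn independently.  The RNG
#' state is saved and restored, and the output is byte-identical across
#' runs with the same spec.
#'
#' @param spec a [cohort_spec()].
#' @param dist_cm,dist_dp optionally precalibrated [calibrate_tat_distribution()]
#'   results (recomputed from the spec's targets when `NULL`).
#' @return validated case data.frame (see [validate_cases()]), sorted by
#'   receipt date within group.
#' @export
generate_cohort <- function(spec = cohort_spec(), dist_cm = NULL, dist_dp = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(dist_cm)) dist_cm <- calibrate_tat_distribution(spec$tat_target_cm)
  if (is.null(dist_dp)) dist_dp <- calibrate_tat_distribution(spec$tat_target_dp)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(spec$seed)

  cm <- .generate_group(spec$n_cm, spec$year_cm, "CM", dist_cm, spec)
  dp <- .generate_group(spec$n_dp, spec$year_dp, "DP", dist_dp, spec)
  cohort <- rbind(cm[order(cm$receipt_date), ], dp[order(dp$receipt_date), ])
  validate_cases(cohort, year_cm = spec$year_cm, year_dp = spec$year_dp)$cases
}

#' Read a cohort spec from a YAML or JSON config file
#'
#' Scalar fields override the defaults of [cohort_spec()]; TaT targets are
#' given as mappings with keys mean, sd, median, q25, q75, min, max.
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return a `cohort_spec`.
#' @export
cohort_spec_from_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (f in c("n_cm", "n_dp", "year_cm", "year_dp", "monthly_weights",
              "pathologist_split", "slide_probs", "area_probs", "seed")) {
    if (!is.null(cfg[[f]])) args[[f]] <- unlist(cfg[[f]])
  }
  for (f in c("tat_target_cm", "tat_target_dp")) {
    if (!is.null(cfg[[f]])) args[[f]] <- do.call(tat_target, as.list(unlist(cfg[[f]])))
  }
  do.call(cohort_spec, args)
}
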