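---
title: "Comparing pathology workflow efficiency with pathflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing pathology workflow efficiency with pathflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathflow)
```

## The problem

A pathology department switching from conventional microscopy (CM) to
digital pathology (DP) can measure the effect with surprisingly little
data: one row per biopsy case carrying its receipt date, report date, the
diagnosing pathologist, a slide-count category and a case-area category.
From those endpoints alone `pathflow` derives three efficiency views — the
turnaround-time (TaT) distribution, the daily census of pending cases per
pathologist, and a workload calendar relative to theoretical diagnostic
capacity — plus an exploratory equipment cost model. This vignette records
the modelling conventions, the parameters that matter, and the choices made
where the design was genuinely open.

## Turnaround time

TaT is integer-valued in calendar days with minimum 1:

$$\mathrm{TaT} = (\text{report date} - \text{receipt date}) + 1.$$

A same-day sign-out therefore counts as one day. Some convention is forced
once a minimum TaT of one day is admitted; this one keeps the identity
`TaT = report - receipt + 1` uniform across all cases, and it pairs
naturally with the census convention below (a TaT-1 case burdens no day's
backlog).

Summaries report n, mean, SD, median, quartiles and range. Sample quantiles
use linear interpolation between order statistics (R's default type 7); no
convention is canonical for laboratory data and the choice is configurable
in the sense that all raw values are exported.

The two-group comparison uses:

* **Welch's unequal-variance t test**, two-sided. The group variances of
  the two workflows differ materially (the digital group is both faster and
  tighter), so the pooled-variance Student test would be the wrong default.
* **Mann–Whitney U**, two-sided, computed from midranks (exact under
  ties). For pooled sizes n₁+n₂ ≤ 12 the p-value is an exact permutation
  probability over all `choose(n1+n2, n1)` group assignments, using the
  symmetric deviation `|U - n1*n2/2|` as the test statistic; beyond that,
  the tie-corrected normal approximation with continuity correction. The
  test suite asserts the two routes agree within 0.02 at n₁ = n₂ = 6 and
  that the approximation matches `wilcox.test` exactly.

The TaT–slide-count association maps the four slide bins (1, 2, 3–4, ≥5)
to ordinals 1–4 and computes Spearman's rho on tie-corrected midranks. A
2×k chi-square/Fisher utility for categorical composition is exposed for
completeness but drives no headline result.

No multiple-testing adjustment is applied across strata; the stratified
tables are descriptive.

## The daily pending-cases census

For each calendar day *d* and pathologist *p*, the census counts cases with

$$\text{receipt} \le d < \text{report},$$

i.e. a case is pending on its receipt day and no longer pending on its
report day. The half-open convention is the one under which a same-day
(TaT = 1) case contributes zero backlog — consistent with same-day
resolution. The census is computed by a sweep line: +1 in a difference
array at the (clipped) receipt index, −1 at the (clipped) report index,
then prefix sums. The matrix is per calendar year; cases reported in the
next year stay pending through December 31, and weekends and holidays are
ordinary days. The suite proves the sweep line identical to brute-force
day-by-day counting (exhaustively on small instances, and on 100 random
500-case cohorts) and checks exact pending-days conservation

$$\sum_d \text{count}(d,p) \;=\; \sum_{\text{cases of } p}
  \big[\min(\text{report}, \text{Jan 1}^{+}) - \text{receipt}\big]_+ .$$

## Workload calendar and reduction

Theoretical daily diagnoses = annual assigned caseload / annual working
days. The default working year is 220 days (a standard European hospital
contract after weekends, leave and public holidays); the caseload defaults
to each pathologist's observed annual case count. Roughly 60% of working
time goes to diagnosis; that fraction does not alter the capacity ratio but
is carried so the index can also be read as the share of a working day the
backlog represents (`day_share = index × 0.6` ÷ 1). The workload index is
pending count ÷ daily capacity, so index > 1 means more than a day's
diagnostic work is queued.

The year-over-year reduction is

$$100\left(1 - \frac{\overline{\text{index}}_{\text{DP}}}
  {\overline{\text{index}}_{\text{CM}}}\right),$$

averaged over matching calendar months (month *m* of the first year against
month *m* of the second) and unweighted across pathologists. Because the
same capacity constant appears in numerator and denominator, the reduction
is invariant to it — a property the tests assert — so the unprinted
capacity inputs cannot bias the headline percentage. A per-month reduction
table is always emitted alongside the annual figure.

## Equipment cost model

Two scenarios: *replacement* (only CM equipment newly purchased within the
analysis horizon is charged; the amortized microscope stock is free) and
*new laboratory* (every CM item is charged as a base-year purchase). Two
modes:

* **acquisition** — sums purchase prices of in-horizon items; this is the
  arithmetic behind the headline scenario totals, and it is what the
  acceptance tests pin down.
* **depreciated** — spreads each non-one-off purchase over a 6-year
  straight line and discounts costs from 2022 onward at 3% per year toward
  the 2021 base year; one-off items are charged at acquisition,
  undiscounted in the base year. How depreciation and discounting interact
  with the printed scenario totals is not spelled out anywhere, so this
  mode is offered as the economically orthodox alternative rather than as
  the source of the headline numbers.

Annualization divides the cost difference by the horizon length (5 years,
2021–2025 inclusive) and rounds half-up to whole euros — the convention
consistent with both headline annual figures. The packaged
`default_inventory()` is a *synthetic* parts list: eight microscopes at
€1,875 (two bought in-horizon), and a scanner bundle plus nine €2,500
workstations summing to €164,388. The per-item split is a plausible
invention reproducing the workflow totals, not a published list; any real
inventory can be supplied as CSV. The cost per percentage point of
workload freed is the annual over-run divided by the percent reduction,
rounded half-up.

## The synthetic cohort generator

The generator's defaults define the study conditions: 5,836 CM cases
received in 2021 and 6,086 DP cases in 2022 (11,922 in total); monthly
arrival weights uniform except July and August at 60% of the uniform
share, renormalized (the summer dip characteristic of this setting — the
precise depth is not published, and 60% is a single choice, not a tuning
knob); a 50/50 pathologist split (per-pathologist case shares are not
published; only pending-census averages are); slide-category probabilities
36.74 / 21.56 / 22.48 / 19.22%; and six case-area categories with
probabilities (18, 27, 22, 18, 3, 12)% chosen as a plausible biopsy mix for
a general department (dermatopathology largest, neuropathology rare) —
the published composition table is not available in text form.

TaT is drawn from a **discretized two-component gamma mixture** on integer
days 1..max: `pmf(k) ∝ F(k) − F(k−1)` with F the mixture CDF, truncated
and renormalized. A single two-parameter family cannot match mean, SD,
median and both quartiles simultaneously; the mixture's five parameters
can. Calibration minimizes the sum of squared discrepancies standardized
by the acceptance tolerances (±0.1 day mean, ±0.2 SD, ±1 day on median and
quartiles), by Nelder–Mead from a fixed grid of six starting points
(mixture weights 0.35/0.5/0.65 × component spreads 1.6/2.5 around the
moment-matched single gamma), so the fit is deterministic and cached per
session. Distribution quantiles are read off a piecewise-linear CDF
anchored at F(0) = 0 — the discrete analogue of the interpolation
convention used for sample quantiles. An infeasible target (e.g. quartile
spread incompatible with the SD) raises a calibration error carrying the
best achieved discrepancies. The degenerate near-point-mass limit (all
location targets equal, SD → 0) is handled by the same machinery.

Receipt dates are drawn month-first (multinomial on the weights), then
uniformly within the month; `report = receipt + TaT − 1`; pathologist,
slide category and area are independent draws. Everything is reproducible
from the spec's single seed (the generator saves and restores the global
RNG state).

What the generator deliberately does **not** emulate: within-year TaT
drift (a learning curve in the first digital year would make early months
slower — TaT here is independent of receipt month), holiday closures or a
zero-backlog reset around holidays, case reassignment between
pathologists, per-pathologist or per-area TaT differences beyond the group
targets (strata are exchangeable), and intra-laboratory queueing stages
(accessioning, staining, scanning) — the data model has endpoints only.
Passing tests on synthetic cohorts therefore validate the *pipeline
arithmetic* under realistic marginals, not the idiosyncrasies of any real
department's case flow; in particular, per-pathologist census means and
peaks depend on arrival/assignment details that are not identifiable from
published group summaries, so they are checked for structural coherence,
not pinned to external values.

## Validation and degenerate inputs

Case tables are validated by *exclude-and-report*: any row with a missing
field, an unknown label, or report < receipt is dropped and itemized with a
reason, mirroring how incomplete cases leave a retrospective analysis set;
the reader never aborts on a bad row. The counts always reconcile
(`n_input = n_excluded + n_analyzed`) and the package reports raw counts
without forcing them to match any externally stated totals. A methodology
label inconsistent with the receipt year of the two-year design is flagged
but kept. Degenerate analytic inputs are flagged rather than fatal where a
flag is meaningful (identical groups in the comparison, constant TaT in the
rank association, zero capacity or zero reference workload), and are errors
where no meaningful result exists (empty input file, mismatched pathologist
sets, non-positive workload reduction in the cost-per-point division).

## Problem sizes in the test suite

Module tests run on cohorts of a few hundred cases and random censuses of
200–500 cases; the calibration-facing checks use the full default cohort
(11,922 cases), which generates in about two seconds once the two
distribution calibrations (a few seconds each, cached) are done. The
parameter-recovery check injects a known DP/CM pending-days ratio
r ∈ {0.5, 0.708, 0.9} by randomized rounding of scaled per-case pending
days — keeping the expected pending-days at exactly r times the original —
and recovers the implied reduction 100(1−r)% within 1.5 percentage points,
a band covering Monte-Carlo noise plus the small year-end clipping bias
(clipping trims long conventional intervals slightly more than their
scaled digital counterparts).

## Known limitations

* Endpoints only: no service-time decomposition, so "workload" is a backlog
  proxy, not measured effort.
* The census treats all 365 days alike; real sign-out happens on working
  days, so weekend census levels are interpolations of the surrounding
  weekdays.
* The depreciated-discounted cost mode and the acquisition mode answer
  different questions; only the latter reproduces simple scenario sums.
* The generator's stratum exchangeability means stratified TaT tables on
  synthetic data differ only by sampling noise — useful as a null, but not
  a model of real heterogeneity.
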