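---
title: "Methods: cost-minimization modelling of an IV-to-SC trastuzumab switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-minimization modelling of an IV-to-SC trastuzumab switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trastucost)
```

## The modelling question

Trastuzumab for HER2-positive early breast cancer exists in two
formulations with very different resource profiles. The intravenous (IV)
form is dosed by body weight (a larger loading dose, then maintenance
doses), must be compounded per patient, and occupies an infusion chair for
30–90 minutes. The subcutaneous (SC) form is a fixed 600 mg dose injected
in about 5 minutes with no loading dose. The two are clinically
equivalent for this indication, which makes the comparison a
*cost-minimization* problem: only costs differ, so the analysis reduces to
careful accounting plus one structural question — at what cohort mean
weight does fixed-price SC dosing stop being more expensive than
weight-proportional IV dosing?

trastucost models a treated cohort under three counterfactual scenarios
(all IV; all SC; IV while on chemotherapy then SC) and accounts for four
additive cost components per cycle: drug acquisition, preparation-stage
drug waste, preparation labour, and outpatient-clinic (chair) occupancy.

## Model structure and assumptions

**Cohort representation.** A tidy patient-phase table: each row is one
contiguous run of cycles at one cadence (`weekly`, given with
chemotherapy, or `q3w` afterwards) with at most one loading cycle. This is
the minimal structure that supports all three scenarios: the weekly/q3w
distinction determines which cycles switch formulation in scenario 3 and
which convert 3:1 in scenario 2.

**Dosing.** IV doses are exact weight × mg/kg products: preparation is
assumed robotic, drawing exact amounts, so no vial rounding is applied.
The weekly coefficients are 4/2 mg/kg (loading/maintenance). The q3w
coefficients default to the label-standard 8/6 mg/kg; they are exposed in
`dose_schedule()` because they are an assumption, not an institutional
measurement, and the break-even result is mildly sensitive to the loading
coefficient (the calibrated intersection moves within roughly 64.9–65.2 kg
across defensible choices).

**Cycle conversion.** Replacing weekly IV cycles by q3w SC cycles uses
ceiling division per weekly block, `ceil(n/3)`: a partial block of one or
two remaining weekly cycles still requires one SC administration. Loading
events are treated as data — part of the recorded phase — and are never
synthesized or removed by the conversion; the first converted cycle of a
block that contained a loading keeps the label for bookkeeping only (an SC
cycle is pharmacologically identical regardless of label).

**Costs.** All arithmetic is unrounded internally; rounding to printed
precision (euros to the unit, hours to the hour, percentages to one
decimal) happens only in `format_report_tables()`. Waste applies only to
IV drug spend, as a fixed fraction (default 0.11%); the SC syringe is
prefilled and wastes nothing in this model. Per-patient breakdowns
attribute each cycle's costs to its patient, and waste proportionally to
the patient's IV drug spend, so patient vectors sum exactly to scenario
totals (an invariant the test suite asserts).

**Preparation time: effective versus unit.** The source aggregates carry
two mutually inconsistent sets of preparation times: measured
per-preparation robot times (844 s IV, 641 s SC) and overall workloads
(120 h across 1,292 IV cycles; 34 h across 937 SC cycles) that imply about
334 s and 131 s per cycle. The package carries both. Workload and cost
aggregation use the *effective* per-cycle seconds (defaults
`120*3600/1292` and `34*3600/937`), which reproduce all three scenarios'
overall hours self-consistently, including the mixed scenario. The unit
seconds are retained in `unit_costs()` solely for the per-cycle
reduction statistic (641/844 ≈ a 24.1% shorter preparation). The
discrepancy is documented rather than hidden; likely the overall
figures net out parallelized or batched steps.

Per-cycle preparation costs are taken as the printed €8.17 / €6.99
constants. They cannot be re-derived from the stated technician/pharmacist
rates under any single-rate assumption, so the staff rates remain in the
configuration for sensitivity use only.

## The break-even model

With the cycle structure frozen, each scenario's cost is affine in mean
body weight: IV drug and waste scale with weight; SC drug, preparation and
clinic occupancy do not. The form is deliberately minimal — two straight
lines and their intersection:

- slope (scenario 1) = IV price × per-kg dose total × (1 + waste
  fraction), where the per-kg dose total is the count-weighted sum of
  mg/kg coefficients over the cycle structure (`calibrate_per_kg()`);
- the cohort's mean weight is *derived* (total IV mg ÷ per-kg dose total),
  never assumed, and is reported with the fit.

`breakeven_weight()` handles the degenerate cases explicitly: parallel
curves with different intercepts have no break-even (`NA`); identical
curves break even over the whole validity range (returned as a range).
The mixed scenario is excluded from the default break-even fit — it is
dominated on both cost and time in this setting — but `cost_curve()`
supports building its curve if wanted.

## Statistical comparison

The scenarios are counterfactual treatments of the *same* patients, i.e.
correlated samples. The replicated analysis nevertheless used
independent-groups one-way ANOVA with Bonferroni-adjusted pairwise
pooled-variance t-tests, so that is the default in `compare_scenarios()`;
a one-way repeated-measures decomposition (subject sum of squares removed,
`(n-1)(k-1)` error degrees of freedom) is available as
`method = "repeated"`. Degenerate inputs have defined conventions: all
observations identical gives F = 0, p = 1; zero within-variance with
non-zero between-variance gives F = Inf, p = 0. Post-hoc tests are
computed but flagged `gate_passed = FALSE` when the omnibus p-value is not
below the threshold, mirroring the conventional gatekeeping. The
implementation is an authored sum-of-squares decomposition; the tests
cross-check it against `stats::aov`, `stats::t.test` (F = t² on two
groups) and `stats::pairwise.t.test` as independent oracles.

## The synthetic-cohort generator

`generate_cohort()` stands in for an unreleased institutional extract. It
emulates the *aggregate* structure of that cohort:

- body weights from a truncated log-normal (`meanlog = log(63.75)`,
  `sdlog = 0.229`, truncated to 42–95 kg), matching the printed median and
  quartile bounds of 55 / 63.75 / 74.9 kg;
- a per-patient phase trajectory drawn from a scheme mix derived from the
  published chemotherapy regimen frequencies (weekly-taxane regimens →
  weekly-then-q3w trastuzumab, 96/114; others → q3w-only, 18/114);
- early discontinuation with probability 0.035 (the observed
  cardiotoxicity interruption rate);
- calendar-window censoring: about a quarter of patients
  (`carryover_fraction = 29/114`) are mid-course when the observation year
  opens, so their loading cycle is unobserved — which is how 114 patients
  can contribute only 85 loading cycles — and late starters are cut at the
  window end.

The completed-course cycle counts (`weekly_cycles_full = 12`,
`q3w_after_weekly = 6`, `q3w_cycles_full = 12`) are calibration
parameters: they were fixed once by Monte-Carlo simulation so that the
expected total cycle count over many seeds lands within 10% of the 1,292
reference cycles, and they should be read as effective within-horizon
course lengths, not as clinical treatment durations (a full adjuvant year
would be longer, but then a one-year observation window would record
correspondingly fewer of its cycles per patient than the reference
aggregate shows under this start-time model).

What the generator does *not* emulate: per-patient correlation between
weight and regimen, seasonal patterns in treatment starts, re-loading
after treatment gaps, and any clinical outcome. Passing tests on
synthetic cohorts therefore demonstrate correctness of the accounting and
calibration machinery, not fidelity to any real institution's casemix.

The bundled `example_cohort()` is different in kind: a *constructed*
114-patient table (labelled synthetic in its filename) whose aggregates
match the printed reference structure exactly — 53/490 weekly and 32/717
q3w loading/maintenance cycles, weekly blocks converting to 188 SC cycles
(937 total), and weights solved so total IV mass is 372,214 mg with the
weekly-phase portion at 77,710 mg. It is the desk-scale fixture on which
the package reproduces the published aggregate economics.

## Numerical choices

- Quartile bounds use linear-interpolation percentiles
  (`stats::quantile`, type 7); the reference table's "quartiles" are read
  as Q1/Q2/Q3 bounds plus the maximum.
- Cost additivity is exact by construction; tests assert it at 1e-9
  relative tolerance to allow only for float summation order.
- Reports are serialized with full numeric precision; non-finite values
  (e.g. an undefined SD for a one-patient cohort) round-trip through an
  explicit string encoding. Files are written to a temporary name and
  renamed, so a failed write never leaves a truncated report.
- Determinism: all generator randomness flows from one integer seed;
  identical configurations produce byte-identical JSON reports (asserted
  in the tests).

## Known limitations

- The per-patient cost dispersions (SDs) depend on the true patient-level
  distribution, which was never published; they are computed from
  whatever cohort is supplied and are not comparable to the printed ±
  values. Several printed aggregates (the mixed scenario's waste basis,
  overall-cost block, per-patient mean hours) are internally inconsistent
  with their own components and are deliberately not reproduced.
- The break-even model is cohort-level (mean weight), matching its source;
  it says nothing about which individual patients are cheaper on SC.
- Indwelling-catheter costs, staffing/queueing dynamics and clinical
  outcomes are out of scope.
- Problem sizes throughout the tests are desk-scale by design: the
  114-patient reference table, tiny hand-built cohorts for oracle
  comparisons, and 200-seed Monte-Carlo checks of generator calibration.
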