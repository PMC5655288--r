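# trastucost

Cost-minimization modelling of intravenous (IV) versus subcutaneous (SC)
trastuzumab in early breast cancer, for hospital pharmacists, oncology
day-hospital managers and health-economics analysts who need to quantify
what a route-of-administration switch does to drug spend, pharmacy workload
and infusion-chair time.

## The model

A cohort of treated patients is described as patient-phase records: each
phase is a run of trastuzumab cycles at one cadence, `weekly`
(chemo-concurrent) or `q3w` (every three weeks), with at most one loading
cycle. Three counterfactual treatment scenarios are evaluated over the same
cohort:

1. **Scenario 1 — all IV.** Weight-based dosing: 4/2 mg/kg
   loading/maintenance weekly, 8/6 mg/kg q3w; administration 90 min
   (loading) or 30 min (maintenance).
2. **Scenario 2 — all SC.** Fixed 600 mg dose, 5 min administration, no
   loading dose; each weekly block of *n* IV cycles becomes ⌈*n*/3⌉ SC
   cycles, q3w cycles convert 1:1.
3. **Scenario 3 — IV during chemotherapy, then SC.** Weekly phases stay IV,
   q3w phases switch to SC 1:1.

Per scenario, total cost decomposes additively as

```
global = drug + waste + preparation + clinic
```

with drug cost at €4.15/mg (IV) and €2.87/mg (SC), preparation-stage waste
as 0.11% of IV drug spend, preparation labour at €8.17 (IV) / €6.99 (SC)
per cycle, and clinic occupancy at €89.80 per chair hour.

Holding the cycle structure fixed, each scenario's total cost is affine in
the cohort's mean body weight `w`:

```
C1(w) = p_iv * (1 + f_waste) * D * w + (prep1 + clinic1)        D = Σ cycles × (mg/kg)
C2(w) = 600 * n_sc * p_sc + prep2 + clinic2                     (slope 0)
```

The break-even weight is the intersection `w*` of the two lines: above it,
fixed-dose SC treatment is cheaper than weight-based IV treatment.
Scenario comparisons use one-way ANOVA on per-patient cost (or time)
vectors with Bonferroni-adjusted pairwise post-hoc t-tests.

A synthetic-cohort generator (`generate_cohort()`) emulates the aggregate
structure of the 2014 institutional cohort the model was built on
(truncated log-normal weights, scheme mix from published regimen
frequencies, calendar-window censoring), and a bundled 114-patient
reference table (`example_cohort()`, constructed, labelled synthetic)
reproduces its printed cycle structure exactly.

## Worked example

```r
library(trastucost)

cohort <- example_cohort()
summarize_cohort(cohort)[, c("n_patients", "total_iv_cycles",
                             "loading_cycles", "weekly_cycles")]
#> # A tibble: 1 × 4
#>   n_patients total_iv_cycles loading_cycles weekly_cycles
#>        <int>           <dbl>          <dbl>         <dbl>
#> 1        114            1292             85           543

evaluate_scenario(cohort, 1)
#> Scenario 1 over 114 patients
#>   drug 1,544,688 + waste 1,699 + prep 10,556 + clinic 65,644 = global 1,622,587 EUR
#>   prep 120.0 h, chair 731.0 h; mean global 14233.2 EUR/patient

evaluate_scenario(cohort, 2)
#> Scenario 2 over 114 patients
#>   drug 1,613,514 + waste 0 + prep 6,550 + clinic 7,012 = global 1,627,076 EUR
#>   prep 34.0 h, chair 78.1 h; mean global 14272.6 EUR/patient

fit_breakeven_cohort(cohort)
#> Break-even cost model (affine in mean body weight)
#>   scenario 1: 23888.75 EUR/kg x w + 76199.44 EUR
#>   scenario 2: 0.00 EUR/kg x w + 1627075.51 EUR
#>   implied mean weight: 64.73 kg; break-even at 64.92 kg
```

Reading: switching the whole cohort to SC raises drug spend (fixed 600 mg
exceeds the weight-based dose for most patients here) but collapses
preparation hours 120 → 34 and chair hours 731 → 78, so the global means
per patient differ by only ~€39; for a cohort mean weight above ~65 kg the
SC scenario becomes the cheaper one. `autoplot()` on the break-even model
draws the two cost lines; `tidy()`/`glance()` give tabular views of every
fitted object.

A full pipeline run (tables, break-even curve, ANOVA comparisons, JSON
report) is one call:

```r
report <- run_pipeline(run_config(cohort = example_cohort()))
write_report(report, "report.json")
```

or from the shell via the thin CLI front-end `inst/cli/ivsc-cost.R`
(`run`, `breakeven`, `synth` subcommands).

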