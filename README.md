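# twovisit

Statistical analysis of **two-visit (pre–post) chronic-disease monitoring
cohorts** with two care groups — the setting of care-pathway effectiveness
studies in which patients followed by a general monitoring programme
(`PDTA`), some of whom are additionally enrolled in a specialised care plan
(`PDTA_CAD`), are examined at baseline and again about a year later across
17 clinical and biochemical outcomes.

The package is aimed at biostatisticians and epidemiologists who need the
full pipeline for this design:

* **Random-intercept linear mixed model** (written from scratch, validated
  against `lme4`): for outcome *y* of subject *i* at visit *j*,

  *y<sub>ij</sub>* = *x<sub>ij</sub>*ʹβ + *b<sub>i</sub>* + *e<sub>ij</sub>*,
  with *b<sub>i</sub>* ~ N(0, σ<sub>b</sub>²), *e<sub>ij</sub>* ~ N(0, σ<sub>e</sub>²).

  Estimation profiles the (restricted) likelihood over the variance ratio
  σ<sub>b</sub>²/σ<sub>e</sub>² with closed-form GLS at each step; inference is by
  two-sided Wald z tests. Model 1 fits time only; Model 2 fits time, care
  group, and group×time — whose coefficient is the between-group difference
  in mean change, the effectiveness contrast of a pre–post design.
* **Descriptive group comparisons**: median (IQR) and count (percent)
  tables with Kruskal–Wallis and uncorrected Pearson chi-square tests.
* **Benjamini–Hochberg** false-discovery-rate adjustment of each effect
  column across the 17 outcomes.
* **Monte Carlo power / sample-size engine** for the design, simulating
  Y = 51 + 2.6 T + 2.6 G + 2.6 TG (total SD 3.3, ICC 0.55; Cohen's
  d = 2.6/3.3 ≈ 0.8 per term) and testing at the multiplicity-adjusted
  α = 0.05/17 — plus an independent closed-form analytic oracle.
* **Synthetic cohort generator**: two-visit cohorts with configured group
  sizes (default 91/33), marginal medians/IQRs, within-subject correlation
  and *exact* per-variable missing-value counts.

## Worked example

```r
library(twovisit)

coh <- generate_cohort(cohort_config(seed = 1))   # 124 subjects, 248 visits
rep <- run_full_analysis(coh)
rep$longitudinal[1:3, c("outcome", "m1_est", "m1_se", "m1_p", "m1_p_adj")]
#>            outcome   m1_est   m1_se    m1_p m1_p_adj
#> 1            hba1c -0.00409 0.00181 0.02337   0.0993
#> 2 microalbuminuria -0.00752 0.02249 0.73809   0.7381
#> 3 creatinine_...   -0.00487 0.00367 0.18445   0.4390
```

`m1_est` is the Model-1 time effect **per day of follow-up**: the fitted
−0.0041 mmol/mol/day for glycated haemoglobin corresponds to ≈ −1.5
mmol/mol over the median 370-day interval; its raw Wald p-value 0.023
rises to 0.099 after Benjamini–Hochberg adjustment across the 17 outcomes,
so it would not survive multiplicity control. The report also carries the
three Model-2 blocks (`m2_time_*`, `m2_group_*`, `m2_inter_*`) and the
per-visit descriptive tables (`rep$baseline_table`, `rep$followup_table`).

Power of the design at n = 124 (62 per group):

```r
pc <- power_config(reps = 500, seed = 1)
analytic_power(pc)$joint
#> [1] 0.8718905
run_power_simulation(pc)
#> Monte Carlo power (500/500 replications converged, alpha = 0.00294)
#>   group        0.930 (MC SE 0.011)
#>   time:group   0.922 (MC SE 0.012)
#>   joint        0.852 (MC SE 0.016)
```

The joint rate — both the group and group×time terms significant in the
same replication — is the design's headline operating characteristic:
about 87% (the Monte Carlo estimate fluctuates by ±1.5 points at 500
replications around the analytic value 0.872).

Command-line wrappers over these functions live in `inst/scripts/`
(`simulate-cohort.R`, `power.R`, `analyze.R`).

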