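# aabalance

Amino acid mass balance, dialysis kinetics, and fatigue associations in
chronic hemodialysis cohorts.

Hemodialysis removes free amino acids into the spent dialysate at every
session. Because treatment is intermittent (2–3 sessions/week) while diet is
continuous, and because many patients retain some residual kidney function,
the clinically meaningful quantity is the **daily** loss:

```
daily loss_x (µmol/24 h) = (V_dial × D_x × n) / 7 + UE_x
```

with `V_dial` the spent dialysate volume (L), `D_x` the pooled-dialysate
concentration (µmol/L), `n` sessions per week, and `UE_x` the 24-h urinary
excretion (0 for anuric patients). Controls lose only
`V_urine × U_x`. `aabalance` implements this mass-balance accounting per
patient along with the surrounding clinical kinetics and statistics:

* **Registry** of the 21 reported amino acids (9 essential incl. the three
  BCAAs, 12 non-essential) with free-molecule molecular masses for µmol → g
  conversion; cysteine and aspartic acid are explicit excluded analytes.
* **Kinetics**: single-pool Daugirdas Kt/V
  (`−ln(R − 0.008 t) + (4 − 3.5 R)·UF/W`), Maroni protein intake from total
  urea appearance (dialysis + urine variants), dialytic clearance in mL/min
  and fractional clearance relative to creatinine.
* **Cohort statistics**: mean ± SD vs median (IQR) dispatch, Welch
  t/Wilcoxon/chi-squared two-group tests, paired tests, and the published
  derived display columns (proportional difference, loss ratio,
  intradialytic proportional change) with their exact rounding conventions.
* **Fatigue models**: severe fatigue = CIS subjective score ≥ 35; logistic
  regressions per SD or per doubling with two adjustment models, Wald CIs,
  VIF diagnostics, a five-rule sensitivity-exclusion suite, standardized-beta
  determinant analysis, and inverse-logit probability curves.
* **Synthetic cohorts**: a seeded generator whose defaults are
  moment-matched to the published summary tables (59 patients, 33 controls,
  log-normal analyte models, back-solved dialysate panels so mass balance is
  exact, Daugirdas-consistent urea ratios, calibrated fatigue prevalence).

## Worked example

```r
library(aabalance)

ktv_daugirdas(R = 0.3, t = 4, UF = 2.0, W = 78)
#> [1] 1.392409

cohort <- generate_cohort(default_config(seed = 1))
cohort
#> <aa_cohort> 59 hemodialysis patients, 33 controls; 22 analytes; seed 1

q <- quantify_cohort(cohort)
dplyr::summarise(dplyr::group_by(q$per_subject, arm),
  daily_loss_g = mean(loss_total_g),
  pct_of_intake = mean(pct_of_intake),
  protein_intake_g = mean(protein_intake_g))
#> # A tibble: 2 × 4
#>   arm     daily_loss_g pct_of_intake protein_intake_g
#>   <chr>          <dbl>         <dbl>            <dbl>
#> 1 control        0.622         0.845             79.7
#> 2 hd             4.13          6.49              70.2
```

At the study's sample size the simulated patients lose ~4.1 g of amino acids
per day (~6.5% of their protein intake) versus ~0.6 g (~0.8%) in controls —
the roughly 7-fold absolute and 10-fold relative excess that motivates the
analysis. The comparison tables and fatigue models follow the same objects:

```r
t3 <- build_table(cohort, 3, q)
t3[t3$analyte %in% c("taurine", "proline", "total"),
   c("analyte", "hd_display", "ctrl_display", "derived", "p")]
#> # A tibble: 3 × 5
#>   analyte hd_display      ctrl_display   derived        p
#>   <chr>   <chr>           <chr>            <dbl>    <dbl>
#> 1 proline 3750 ± 1600     8.17 ± 3.62      459   2.48e-25
#> 2 taurine 102 (29.1; 447) 508 (281; 729)     0.2 6.87e- 4
#> 3 total   33000 ± 9040    5310 ± 2080        6   2.63e-33

ds <- association_dataset(cohort, q)
fit_logistic(ds, "loss_taurine", model = 2, transform = "log2")[,
  c("predictor", "increment", "or", "ci_lo", "ci_hi", "p")]
#> # A tibble: 1 × 6
#>   predictor    increment    or ci_lo ci_hi      p
#>   <chr>        <chr>     <dbl> <dbl> <dbl>  <dbl>
#> 1 loss_taurine per-log2  0.773 0.615 0.972 0.0274
```

`derived` is the loss ratio with its display rounding (one decimal below 2,
integer above); the odds ratio reads: each doubling of the daily taurine
loss is associated with ~23% lower odds of severe fatigue, adjusted for age,
sex, BMI, vintage, hemoglobin, CRP, cardiovascular disease and diabetes.

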