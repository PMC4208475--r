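# cathex — catastrophic household health expenditure analysis

`cathex` measures the incidence, intensity and socioeconomic distribution of
catastrophic out-of-pocket (OOP) household health spending from
complex-survey microdata, for health economists and epidemiologists
analysing household expenditure surveys in settings where care is largely
paid for out of pocket.

A household is *catastrophic* when its 30-day OOP health spending exceeds a
threshold share `z` (default 10%) of its total consumption expenditure. With
budget share `s_i = T_i / x_i`, weight `w_i` and flag `E_i = 1(s_i > z)`,
the package estimates:

- **Headcount** `H = Σ w_i E_i / Σ w_i` with a PSU-clustered linearization SE;
- **Overshoot** `O = Σ w_i (s_i − z) E_i / Σ w_i` and **mean positive
  overshoot** `MPO = O / H` (the identity `O = H·MPO` is asserted on every
  result);
- **Concentration index** `C = 2 cov_w(y, r) / μ` over weighted fractional
  wealth ranks `r` from per-adult-equivalent expenditure, with a
  delta-method (convenient-regression) SE and a PSU-bootstrap percentile
  interval in which ranks are rebuilt inside every replicate;
- **Comorbidity cost attribution**: jointly reported treatment costs are
  allocated to individual illnesses by no-intercept OLS on illness
  indicators, floored at zero and renormalized so allocations conserve each
  group total exactly;
- **Illness-specific risk**: quintile-stratified log-link Poisson models of
  the catastrophe flag with cluster-robust sandwich variance, reported as
  rate ratios with Wald 95% CIs and explicit not-estimable markers.

Because such microdata are confidential, the package includes a synthetic
survey generator (`generate_survey()`) emulating a 100-cluster urban
household survey with known ground truth — constant or wealth-graded
catastrophe probability (for a linear gradient `p(r) = a + b·r` the true
concentration index is `b / (6(a + b/2))`), illness prevalences, and
multiplicative illness rate ratios — so every estimator is validated by
parameter recovery.

## Worked example

```r
library(cathex)
cfg <- analysis_config(seed = 7, bootstrap_reps = 100)
run <- run_pipeline(simulate = true_params(gradient = c(0.19016, -0.10433)),
                    config = cfg)
print(run)
#> <cathex pipeline run>
#>   households analysed : 2000
#>   catastrophic headcount : 12.8%  (overshoot 4.4%, MPO 34.7%)
#>   concentration index    : -0.136 (95% CI -0.194 to -0.077)
#>   aggregated vs disaggregated OOP: z = -0.002, p = 0.998
#>   tables: $table2 (prevalence), $table3 (OOP), $table4 (catastrophe), $table5 (rate ratios)
```

Here 12.8% of households spent more than 10% of their total expenditure on
health in the 30-day window; averaged over *all* households the excess
above the threshold was 4.4% of total expenditure, and among catastrophic
households alone 34.7%. The negative concentration index, with a bootstrap
interval excluding zero, says catastrophic spending concentrates among
poorer households — as it should: this survey was simulated with the
gradient `p(r) = 0.19016 − 0.10433·r`, whose true index is −0.126.

The per-illness view (`run$table4`) applies the same measures to each
illness's allocated costs:

```r
t4 <- run$table4
head(t4[order(-t4$H_pct), c("illness_code","H_pct","C","O_pct","MPO_pct")], 4)
#>        illness_code H_pct      C O_pct MPO_pct
#> 1               any 12.77 -0.136 4.426   34.65
#> 10     hypertension  4.05 -0.406 0.547   13.48
#> 2  cold_cough_fever  2.57 -0.442 0.212    8.24
#> 9          diabetes  2.27 -0.217 0.451   19.87
```

`run$table2` holds illness prevalence by quintile with χ² p-values,
`run$table3` OOP spending components and budget shares by quintile, and
`run$table5` the quintile-stratified Poisson rate ratios. A thin CLI over
the same functions lives at `inst/scripts/cathex.R`
(`Rscript cathex.R simulate|run ...`).

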