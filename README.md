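# thermoparam

Statistical analysis of plasma DSC thermograms for clinical cohorts.

Differential scanning calorimetry (DSC) of blood plasma yields a curve of
excess specific heat capacity versus temperature — a *thermogram* — whose
shape reflects the thermal denaturation of the major serum proteins and
shifts with disease state. `thermoparam` is for biostatisticians and
calorimetry groups who want a reproducible, tested pathway from a matrix of
thermograms plus a clinical table to three families of results:

1. **Group differences** — for each of 23 curve parameters (19 summary
   metrics + 4 principal components), linear models of status
   (control / NED / active) and sex with partial-F model reduction,
   Benjamini–Hochberg FDR across parameters, Tukey-adjusted
   estimated-marginal-mean contrasts, and a median-regression fallback when
   residual diagnostics fail.
2. **Classification** — logistic regression of no-evidence-of-disease (NED)
   vs active disease: VIF ≤ 5 predictor reduction, forward/backward
   stepwise AIC/BIC selection, and 25×5 repeated *stratified*
   cross-validation scored by ROC-AUC.
3. **Survival** — univariate Cox screens with FDR, backward-BIC
   multivariable Cox, Kaplan–Meier curves split at a parameter's median
   with the Mantel–Cox (log-rank) test, and restricted mean survival time
   (RMST, τ = 8 y) with the Greenwood plug-in variance.

The curve parameterization itself is the package core: on the canonical
45–90 °C / 0.1 °C mesh it computes Width (full width at half the global
maximum), Area, Max/T_Max, Median, windowed peaks in 60–66.9 / 67–72.9 /
73–78 °C with a second monotonic-run peak finder as a cross-check, the
valley V1.2 between Peaks 1 and 2, six height ratios, and the first moment
temperature TFM = Σ T·c_p / Σ c_p. A synthetic cohort generator
(three-Gaussian curves, group shifts, a latent shape factor coupled to a
Weibull hazard with log-hazard 0.553 per SD) makes the whole pathway
testable without patient data.

## Worked example

```r
library(thermoparam)

co  <- generate_cohort(cohort_config(seed = 42))   # 49 control / 74 active / 33 NED
m   <- compute_metric_table(co$thermograms)
round(m[1, c("Width", "Area", "Max", "TPeak1", "TPeak2", "V1.2", "TFM")], 4)
#>     Width   Area    Max TPeak1 TPeak2   V1.2     TFM
#> 1 10.6289 2.8831 0.2937   63.1   69.5 0.0835 67.5992

pca <- fit_thermogram_pca(co$thermograms)
pca
#> <thermogram_pca: 5 component(s) kept, first 5 explain 95.2% of variance>

tab <- build_cohort_table(m, pca, co$clinical)
pts <- tab[tab$status != "control", ]
pts$active <- factor(as.integer(pts$status == "active"), levels = 0:1)
cross_validate(pts, "active", c("age", "TPeak2"), repeats = 25, folds = 5, seed = 42)
#> <cv_report: mean AUC 0.7742 over 25 x 5 folds; bal. accuracy 0.641 at threshold 0.5>

act <- tab[tab$status == "active", ]
scr <- cox_univariate_screen(act)
head(scr[order(scr$p), c("parameter", "coef", "hr", "p", "p_adj")], 2)
#>    parameter  coef      hr       p p_adj
#> 23       PC4 6.608 741.043 0.00645 0.094
#> 19       TFM 1.200   3.320 0.00817 0.094
```

Here the first row of the metric table describes one simulated curve
(peak 2 at 69.5 °C, total denaturation enthalpy proxy Area ≈ 2.9 cal/g);
five PCs carry 95% of the curve-to-curve variance; the age + T_Peak2
logistic model separates NED from active at a cross-validated AUC of 0.77
on this synthetic cohort (the generator's effects are deliberately
stronger than clinical ones); and the Cox screen flags the principal
component that the generator's latent survival factor maps onto (PC4 in
this draw, hazard ratio per unit score with FDR-adjusted p = 0.094).

A deterministic worked example uses a reference clinical model
(coefficients 0.0427 per year of age, 0.5010 per °C of T_Peak2), with the
intercept recovered from the model's prediction at the cohort medians:

```r
coefs <- c(age = 0.0427, TPeak2 = 0.5010)
b0 <- calibrate_intercept(coefs, c(age = 57, TPeak2 = 70), 0.741)
round(100 * predict_probability(logistic_model(coefs, b0), c(age = 43, TPeak2 = 70))["probability"], 1)
#> 61.1
odds_interpretation(0.5010)
#> 65   # percent increase in odds of active disease per 1 degC shift in T_Peak2
```

`run_pipeline(pipeline_config(...))` executes every stage in order and
writes tidy CSVs, plots, a run log and an artifact manifest; the thin CLI
`inst/scripts/thermoparam.R` exposes
`simulate | metrics | pca | status | classify | survive | all`.

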