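# seirapls

Chemometric quantification of a drug and its metabolite from
surface-enhanced infrared absorption (SEIRA) spectra, as an R package.

Bisacodyl (BIS) and its deacetylated active metabolite occur in blood at
15–240 ng/mL. Metal-nanoisland substrates amplify their mid-IR bands enough
to measure at those levels (about two-fold on silver, three-fold on gold),
but the two compounds share the pyridine C=N stretch near 1640 cm⁻¹ and
much of the fingerprint region, so neither can be quantified from a single
band. The package implements the full multivariate calibration workflow a
spectroscopist would use, on simulated spectra:

* **Forward model** — Gaussian analyte bands (BIS: 1301, 1640, 1755 cm⁻¹;
  metabolite: 1273, 1640, 3309 cm⁻¹) with linear Beer–Lambert response,
  substrate-dependent plasmonic gain, a plasma background, baseline drift
  and noise, on the 4500→400 cm⁻¹ grid at 1.95 cm⁻¹ spacing.
* **Calibration design** — the 25-mixture multilevel factorial design (5
  levels per analyte over 15–240 ng/mL, balanced and orthogonal) plus a
  random 10-mixture validation set.
* **Preprocessing** — exclusion of the CO₂/humidity regions (4600–4000 and
  2200–1950 cm⁻¹) followed by a segment-wise Savitzky–Golay first
  derivative.
* **PLSR** — NIPALS partial least squares with mean-centering, coefficients
  \(B = W(P^\top W)^{-1}Q^\top\), leave-one-out cross-validation and
  RMSECV-based latent-variable selection (one-SE parsimony rule by
  default).
* **Validation metrics** — RMSEC, SEC, RMSEP, bias, slope/intercept/r/R²,
  percent recovery of spiked samples, and the enhancement factor
  EF = (I_SEIRA/C_SEIRA)/(I_normal/C_normal).

## Worked example

```r
library(seirapls)
demo <- run_demo(seed = 1, replicates = 3)   # protocol default is 45 scans
demo$n_lv
#> [1] 2
summary(demo$model)
#> RMSECV (pooled) by latent-variable count:
#>     lv1     lv2     lv3     lv4     lv5  ...
#> 63.3107  0.2319  0.2387  0.2420  0.2388  ...
#>
#> Calibration figures of merit (concentrations in ng/mL):
#>              BIS metabolite
#> RMSEC     0.2083     0.1914
#> SEC       0.2126     0.1953
#> Bias      0.0000     0.0000
#> Slope     1.0000     1.0000
#> r         1.0000     1.0000
#> R2        1.0000     1.0000
demo$ef
#> $gold
#> [1] 3
#> $silver
#> [1] 2
demo$recovery$BIS
#> $rows
#>         added     found recovery
#> spike01    26  25.83381    99.36
#> spike02   100 100.15735   100.16
#> spike03   236 235.52460    99.80
#> $mean_recovery
#> [1] 99.77333
```

Reading the output: the RMSECV curve collapses from 63 ng/mL at one latent
variable to 0.23 at two — the true chemical rank of a two-analyte system —
and stays flat beyond, so two latent variables are selected. Calibration
bias is exactly zero (a property of mean-centering), errors are a fraction
of an ng/mL at the default 0.5 % noise, the gold and silver substrates show
their three- and two-fold enhancement factors, and spiked plasma samples at
the physiological 26/100/236 ng/mL levels are recovered near 100 %.

Individual stages are exposed for piecewise use: `wn_grid()`,
`simulate_dataset()`, `multilevel_design()`, `preprocess()`, `plsr_fit()`,
`plsr_cv()`, `seira_plsr()` (the fitting front-end, with `predict`,
`summary`, `coef`, `residuals` and `plot` methods), `metrics_report()`,
`recovery_table()`, `enhancement_factor()`, and CSV/JSON readers and
writers for spectra, designs and fitted models. See the vignette
(`vignettes/seira-plsr-workflow.Rmd`) for the model and every default.

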