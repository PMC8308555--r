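# hcymr

Mendelian randomization (MR) of circulating homocysteine (Hcy) on
metabolic syndrome (MetS), as a reusable, tested R pipeline.

Observationally, people with higher homocysteine have more metabolic
syndrome — but that association is confounded (diet, age, lifestyle)
and possibly reverse-causal. MR sidesteps this by using genetic
variants that raise Hcy (notably *MTHFR* C677T, rs1801133) as
instrumental variables: genotypes are randomized at meiosis, so a
variant that raises Hcy and associates with MetS argues for a causal
effect of Hcy itself. hcymr implements the full analysis for
epidemiologists and statistical geneticists:

* **Synthetic cohorts** (`sim_config()`, `simulate_cohort()`,
  `simulate_ld_blocks()`): genotypes in Hardy–Weinberg proportions,
  additive per-allele effects on log-Hcy, a latent confounder, and the
  five MetS components drawn from calibrated logistic liabilities with
  MetS scored by the clinical ≥3-of-5 rule. The causal parameter
  `theta` is, by construction, the marginal log-odds of MetS per 1 SD
  genetically shifted log-Hcy — the estimand every estimator below
  targets.
* **QC and association scans** (`qc_filter()`, `hwe_test()`,
  `linear_assoc()`, `logistic_assoc()`, `observational_or()`,
  `quartile_summary()`).
* **Instrument construction** (`select_instruments()` at strict
  p < 4×10⁻⁸, greedy `ld_clump()` at r² < 0.01, `f_statistic()`,
  `confounder_screen()`, `harmonize()`).
* **One-sample MR** (`wald_ratio()` with delta-method SE, `build_grs()`
  weighted genetic risk scores, `tsls()` two-stage least squares with a
  logistic second stage).
* **Two-sample MR** (`meta_fixed()`, `ivw()`, `weighted_median()`,
  `mr_egger()`, `cochran_q()`, `i2_gx()`, `run_twosample()`), with
  broom-style `tidy()`/`glance()` and `autoplot()`/`plot_mr_scatter()`
  /`plot_mr_funnel()` graphics.

The core two-sample estimator is inverse-variance weighting of the
per-variant Wald ratios β̂_Yi/β̂_Xi,

θ̂_IVW = Σᵢ wᵢ (β̂_Yi/β̂_Xi) / Σᵢ wᵢ,  wᵢ = β̂²_Xi/σ²_Yi,

with the weighted median (robust to <50% invalid weight) and MR–Egger
(free intercept estimating directional pleiotropy) as sensitivity
analyses, plus Cochran Q heterogeneity and I²GX measurement-error
diagnostics. See the methods vignette
(`vignettes/homocysteine-mets-mr.Rmd`) for models, assumptions, and
numerical choices.

## Worked example

Run the whole study on synthetic cohorts at the emulated sizes
(exposure cohort n = 5902; outcome cohorts n = 3693 and 1816; true
causal effect θ = 0.7 log-odds per SD log-Hcy):

```r
library(hcymr)
res <- run_pipeline(list(seed = 5, estimators = list(n_boot = 500)),
                    quiet = TRUE)
print(res)
#> <pipeline_result>
#> <qc_report: 5 in, removed 0 missingness / 0 monomorphic / 0 HWE, 5 retained>
#> instruments retained: rs12567136, rs1801133, rs2336377, rs1836883, rs1624230 (first-stage F = 74.5)
#> one-sample MR:
#>      method estimate ci_low ci_high         p
#>        tsls   0.8174 0.5807   1.054 1.297e-11
#>  wald_ratio   0.7902 0.3606   1.220 3.124e-04
#> two-sample MR:
#> <mr_report: 5 instruments, mode = pool_outcome>
#>           method estimate  ci_low ci_high         p
#>  weighted_median   0.4779  0.1898  0.7660 0.0011487
#>        ivw_fixed   0.4647  0.2237  0.7057 0.0001576
#>         mr_egger   0.5598 -0.1830  1.3026 0.2361401
#> Cochran Q = 2.496 (df 4, p = 0.645); I2GX = 87.2%
```

Reading the output: all five simulated instruments survive QC and
genome-wide selection; the combined first-stage F of 74.5 says weak
instrument bias is not a concern. The one-sample 2SLS estimate of 0.82
log-odds per SD (OR ≈ 2.3) and the two-sample estimates (IVW 0.46,
95% CI 0.22–0.71) bracket the generative θ = 0.7 within their
sampling noise — the two-sample run uses only ~5500 outcome samples, so
its CI is wide. Q's p = 0.645 shows no heterogeneity among the
per-variant ratios (as it should with no pleiotropy simulated), and
the Egger intercept stays near zero.

The packaged five-variant published instrument set (KARE exposure
associations; merged HEXA+CAVAS outcome ORs) flows through the same
machinery:

```r
fx <- hcy_instruments()
run_twosample(fx$exposure, fx$outcome, n_boot = 2000, seed = 1)
#> <mr_report: 5 instruments, mode = pool_outcome>
#>           method estimate  ci_low ci_high      p
#>  weighted_median -0.04508 -0.3149  0.2247 0.7433
#>        ivw_fixed -0.10793 -0.3306  0.1148 0.3421
#>         mr_egger  0.25532 -0.6118  1.1224 0.6043
#> Cochran Q = 4.928 (df 4, p = 0.295); I2GX = 72.2%
```

This run is a smoke-level computation: the published five-SNP MR
results were computed from per-cohort outcome association scans that
were never printed, and the published per-variant table alone does not
regenerate them under any standard estimator — the values above are
what the printed rows actually imply.

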