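---
title: "Mendelian randomization of homocysteine on metabolic syndrome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian randomization of homocysteine on metabolic syndrome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hcymr estimates the causal effect of circulating homocysteine (Hcy, a
methionine-cycle metabolite whose elevation accompanies cardiometabolic
disease) on metabolic syndrome (MetS) using genetic variants as
instrumental variables, and ships a synthetic cohort generator so the
whole pipeline can be exercised and validated without access-controlled
cohort data. This vignette explains the models, the tunable parameters,
the numerical choices, and what the validation does and does not
establish.

## The causal question and the estimators

A variant is a valid instrument if it (i) associates with log-Hcy,
(ii) affects MetS only through Hcy, and (iii) shares no confounder with
MetS. Under these assumptions, with per-allele effects
$\hat\beta_{Xi}$ (SD of log-Hcy) and $\hat\beta_{Yi}$ (log-odds of
MetS), the package provides:

* **Wald ratio** $\hat\theta_i = \hat\beta_{Yi}/\hat\beta_{Xi}$, with
  the first-order delta-method SE
  $\sqrt{\sigma^2_{Yi}/\beta^2_{Xi} + \beta^2_{Yi}\sigma^2_{Xi}/\beta^4_{Xi}}$
  assuming independent numerator/denominator errors (the two-sample
  situation; in one sample the correlation is ignored, a standard
  approximation).
* **IVW**: $\hat\theta = \sum_i w_i\hat\theta_i / \sum_i w_i$ with
  $w_i = \beta^2_{Xi}/\sigma^2_{Yi}$, identical to weighted least
  squares of $\beta_Y$ on $\beta_X$ through the origin. Fixed-effect SE
  by default; a multiplicative random-effects rescaling
  $\max(1,\sqrt{Q/(k-1)})$ is available and suggested by
  `run_twosample()` when the heterogeneity p-value falls below 0.05.
* **Weighted median**: the weighted 50th percentile of the
  $\hat\theta_i$, interpolating the weighted empirical CDF at 0.5 with
  midpoint cumulative weights $s_i = \mathrm{cum}_i - w_i/2$; consistent
  while at least half the weight comes from valid instruments. Its SE
  comes from a seeded parametric bootstrap (2000 draws of
  $\beta^*_{Xi}, \beta^*_{Yi}$ from their sampling distributions);
  2000 is the customary size and puts the Monte-Carlo error on the SE
  near 2%.
* **MR-Egger**: weighted regression of $\beta_Y$ on $\beta_X$ with a
  free intercept after orienting every instrument to the
  exposure-increasing allele ($\beta_X \ge 0$). The slope is the causal
  estimate under the InSIDE assumption; the intercept estimates average
  directional pleiotropy. SEs use the estimated multiplicative
  dispersion $RSS_w/(k-2)$ and both slope and intercept are referred to
  a t distribution with $k-2$ degrees of freedom, the original
  estimator's convention: with well-specified weights the intercept
  (pleiotropy) test then has exactly its nominal size. Flooring the
  dispersion at 1, as some toolkits do, makes that test conservative
  (empirical size nearer 0.02 than 0.05 at $k = 25$), which is why the
  unfloored form is used here.
* **Diagnostics**: Cochran's $Q = \sum_i w_i(\hat\theta_i-\hat\theta)^2$
  against $\chi^2_{k-1}$;
  $I^2_{GX} = \max\{0, (Q_{GX}-(k-1))/Q_{GX}\}$ where $Q_{GX}$ measures
  dispersion of the oriented $\beta_{Xi}$ against their measurement
  error — values near 1 mean regression dilution is not attenuating the
  Egger slope.
* **One-sample MR**: two-stage least squares with a logistic second
  stage — OLS of log-Hcy on the instrument(s) (single variant or a
  weighted genetic risk score) plus covariates, then logistic regression
  of MetS on the fitted exposure plus covariates, rescaled to per-SD
  units. This predictor-substitution procedure is the field's standard
  for binary outcomes but is not exactly the marginal causal log-OR;
  the result carries an `se_method` note, the naive Wald SE ignores
  first-stage noise, and a nonparametric bootstrap is available.

Estimates are reported on the log-odds scale with
$\pm 1.959964\,\mathrm{SE}$ confidence intervals throughout.

## The synthetic cohort generator

`simulate_cohort()` emulates a Korean population-cohort study: an
exposure cohort of 5902 with log-Hcy and MetS, and two outcome-only
cohorts (3693 and 1816) for two-sample MR. The generative model is

$$\log \mathrm{Hcy} = b_0 + \textstyle\sum_i \beta_i g_i + c_X U +
  a\,(\mathrm{age}-58) + s\,\mathrm{male} + \varepsilon,$$

with genotypes $g_i \sim \mathrm{Binomial}(2, f_i)$ (Hardy-Weinberg by
construction), $U \sim N(0,1)$ a latent confounder, and
$\varepsilon \sim N(0, \sigma^2)$. Each of the five MetS components
(central obesity, high triglycerides, low HDL, high blood pressure,
high fasting glucose) is a Bernoulli draw from a logistic liability

$$\mathrm{logit}\,P(C_k = 1) = a_k + \lambda Z + c_Y U +
  \textstyle\sum_i \alpha_i g_i,$$

where $Z$ is cohort-standardized log-Hcy and $\alpha_i$ are optional
direct (pleiotropic) variant effects. MetS is scored exactly as the
clinical rule: present when three or more of the five components are.

**Calibration of the liability slope.** Because the 3-of-5 threshold is
nonlinear, a naive equal split of the causal effect across components
(e.g. $\lambda = \theta/5$) would make the realized exposure-to-MetS
log-odds slope roughly $0.37\,\theta$, leaving $\theta$ without a clean
interpretation. The generator instead solves for $\lambda$ numerically
so that the **marginal log-odds of MetS per 1 SD genetically shifted
log-Hcy equals $\theta$ exactly**: the marginal MetS probability under a
shift $\mu$ is integrated over $(U, \varepsilon)$ on an equal-probability
quadrature grid (40 x 40 Gauss-like nodes via normal quantile
midpoints), the Poisson-binomial tail $P(\text{score} \ge 3)$ is
computed by a 5-step convolution, and a root-finder matches the central
logit-difference slope to $\theta$. Component intercepts $a_k$ are
solved the same way to hit the component prevalence targets; the two
solves are alternated three times, which converges to well below the
Monte-Carlo noise of any downstream use. With this convention $\theta$
is precisely the estimand every MR estimator above targets, which is
what makes parameter-recovery validation meaningful.

**Defaults and their units.** All defaults aim at the published
characteristics of these cohorts:

| parameter | default | unit / rationale |
|---|---|---|
| `n_samples` | 5902 | exposure-cohort size |
| `variants` | 5-SNP panel | the published Hcy instruments, $\beta$ from the association table, East-Asian-like frequencies |
| `theta` | 0.7 | log-odds/SD; near the published two-sample estimates |
| `exposure_intercept` | 2.45 | log-umol/L, puts the median near 2.56 |
| `exposure_noise_sd` | 0.20 | gives total log-Hcy SD about 0.26, matching the printed quartile cut-offs (2.39/2.56/2.74) and hence per-SNP SEs of 0.005-0.008 at n = 5902 |
| `confounder_exposure`, `confounder_outcome` | 0.15, 0.25 | moderate unobserved confounding; induces the usual observational bias without dominating |
| `component_prevalence` | 0.30-0.45 | realistic middle-aged East-Asian component rates; emergent MetS prevalence ~0.29-0.35 |
| `missing_rate` | 0.002 | typical post-genotyping array missingness |
| `alpha_pleiotropy` | 0 | exclusion restriction holds unless violated on purpose |

`component_prevalence` plays the role of the five liability cut-offs,
expressed on the probability scale, which is the scale on which a
practitioner knows them. Observed covariates (age, sex, area, smoking,
drinking, diet score, BMI) are generated with realistic marginals; age
and sex affect the exposure only, so the single latent $U$ is the only
true confounder — exactly the structure the MR identification argument
assumes. The latent $U$ is retained in the phenotype table for
validation. Per-variant direct effects $\alpha_i$ enter each component
liability directly (log-odds per allele on the liability scale); for
small $\alpha$ this is approximately a direct effect on MetS log-odds.

**Seed discipline.** One master seed; each stochastic stage (genotypes,
phenotypes, additional cohorts, bootstraps) derives a child seed by
modular hashing (`derive_seed()`), so any stage can be re-run in
isolation and full runs are bit-identical.

**LD blocks.** `simulate_ld_blocks()` generates blocks of variants whose
tag haplotypes copy the index haplotype's allele with probability
$\sqrt{r^2}$, giving controlled pairwise dosage correlation. It exists
to exercise LD clumping (e.g. 27 candidates in 5 blocks reducing to 5
independent instruments) and is deliberately not a haplotype or
coalescent model: no LD decay, no allele-frequency spectrum.

**What the generator does not emulate.** Real GWAS features that are out
of scope: genotyping batch effects, relatedness and population
structure, imputation uncertainty, winner's-curse selection of
instruments from a genome-wide scan, component-specific causal
structure (the equal-share liability model is a stand-in — the source
analyses report only that two of the five variants associate with
single components), and any exposure measurement-error model beyond
additive noise. Passing tests therefore demonstrate correctness of the
estimators and pipeline under the stated generative assumptions, not
robustness of the scientific conclusion to those real-data
complications.

## QC, association scans and instrument construction

Variants are filtered in a fixed, reported order: missing rate > 0.01,
then monomorphism, then Hardy-Weinberg p < 1e-6 (1-df chi-square with
frequency estimated from counts; a conditional mid-p exact test is
available — the chi-square is the array-QC convention at this
threshold). Association scans are OLS (t reference) and IRLS logistic
(normal reference; convergence when the deviance changes by < 1e-10
within 50 iterations; apparent separation, |beta| > 30, is an error
rather than a silent huge estimate). Missing dosages are dropped
per-variant in regressions but mean-imputed inside generative sums and
risk scores, keeping estimators well-defined without a missingness
model.

Instrument selection keeps variants with exposure p strictly below
4e-8 (a Bonferroni-style genome-wide threshold; a variant exactly at
the threshold is excluded). Greedy clumping iterates by ascending p
(ties broken lexicographically for determinism) and retains a variant
only if its $r^2$ with every retained variant is below the threshold.
The default is 0.01; the source analyses state 0.01 in their methods
but 0.1 in their results, so both are exposed and the discrepancy is
surfaced rather than resolved. Instrument strength is summarized by the
incremental-$R^2$ F-statistic
$F = \frac{R^2_{inc}/(1-R^2_{full})}{k/(n-k-c-1)}$ (equal to the
squared first-stage t for one instrument), with the conventional F < 10
weak-instrument warning. A confounder screen regresses each measured
confounder on each instrument (linear or logistic by type, adjusted for
age/sex/area).

Harmonization aligns outcome to exposure alleles (copy, flip, or drop
as irreconcilable), flags A/T and G/C palindromes and drops them when
MAF > 0.42 (strand unresolvable from frequency; kept-but-flagged when
no frequency is available), then orients every instrument to
$\beta_X \ge 0$. Published outcome ORs are ingested as
$\beta = \ln OR$, $se = (\ln hi - \ln lo)/(2 \times 1.959964)$.

## Numerical and degenerate-input choices

* Quartile boundaries are right-closed (a value equal to a cut-point
  falls in the lower quartile); tied cut-points are an error, not a
  silent empty bin. Identical group means give F = 0 and an ANOVA p of
  1 through the ordinary upper tail.
* Monomorphic input to the HWE test or to `ld_r2()` returns the defined
  boundary value (p = 1, $r^2$ = 0) with an explanatory flag instead of
  NaN.
* $I^2_{GX}$ is truncated below at 0; all-zero exposure SEs define it
  as 1 with a flag.
* The weighted median at $k$ with one instrument holding half the
  total weight returns that instrument's ratio when its midpoint
  cumulative weight spans 0.5; with the heavy instrument at an extreme
  rank the interpolation estimator (the field's standard) can sit
  between neighbours — the estimate always stays inside the range of
  the per-instrument ratios.
* `wald_ratio()` refuses $\beta_X = 0$ and warns below 1 SE of
  instrument strength rather than returning an unstable ratio.
* Fixed-effect meta-analysis of per-variant outcome effects across
  cohorts happens **before** harmonization and MR ("pool outcome"
  mode), matching a merged-cohort outcome table; a
  per-cohort-MR-then-pool mode is provided because summary reports are
  sometimes built the other way, and the two agree asymptotically under
  homogeneity.

## Validation design and problem sizes

The test suite checks every estimator against an independently coded
oracle (weighted `lm`, direct likelihood maximization, explicit loops,
independent CDF interpolation) to 1e-10 on random instances; algebraic
reduction identities (IVW at k = 1 vs the Wald ratio, single-IV F vs
squared t, zero-intercept Egger vs IVW) exactly; and the generator
end-to-end by parameter recovery: 200 replicates of two cohorts of
20,000 with 25 instruments of per-allele effect 0.03-0.06 at
$\theta = 0.7$ give mean bias below 0.05 for IVW, weighted median and
Egger slope, with IVW coverage close to nominal. Diagnostic calibration
(Egger-intercept test size, $Q$ mean $\approx k-1$) runs on 500
summary-statistic replicates, and the weighted median's breakdown
advantage is demonstrated with 40% of instruments given strong
directional pleiotropy. These sizes were chosen to make Monte-Carlo
error comfortably smaller than the tolerances being asserted.

## Known limitations

* The logistic-second-stage 2SLS estimand differs slightly from the
  marginal causal log-OR (non-collapsibility); the package reports it
  because it is the procedure practitioners use, and documents the
  approximation.
* The naive 2SLS SE understates uncertainty; use `boot > 0` for honest
  intervals.
* MR-Egger is subject to regression dilution when the spread of the
  instrument-exposure effects is not large relative to their standard
  errors (the NOME assumption, monitored by $I^2_{GX}$): at
  $I^2_{GX} \approx 0.9$ the slope is attenuated by roughly 10%, so at
  a true effect of 0.7 the Egger estimate centres near 0.63 even though
  the regression itself matches its algebraic oracle exactly. The
  recovery simulations show exactly this: IVW and the weighted median
  centre on the true effect while the Egger slope carries the predicted
  dilution. This is a property of the estimator; the source analyses
  guard against it by reporting $I^2_{GX}$ and interpreting the Egger
  slope only when it is near 1.
* The packaged five-variant set cannot numerically regenerate the
  published five-SNP two-sample MR results, because the per-cohort
  outcome association scans behind those results are not published;
  runs on the fixture are smoke-level computations, not value
  reproductions.
* LD handling is a pairwise-correlation device for clumping; no
  reference-panel LD, no LD-aware estimators.
* No MR-PRESSO/mode-based/multivariable estimators and no genomic
  control or mixed-model GWAS corrections — outside the analysis this
  package implements.
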