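---
title: "Estimating the causal effect of plasma vitamin D on colorectal cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the causal effect of plasma vitamin D on colorectal cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The problem

Observational studies repeatedly find that people with low circulating
25-hydroxy-vitamin D (25-OHD) have a higher risk of colorectal cancer (CRC).
That association cannot, by itself, establish causation: unmeasured
confounders (frailty, time outdoors, diet quality) depress 25-OHD and raise
cancer risk simultaneously, and reverse causation is plausible when blood is
drawn after diagnosis. Mendelian randomization (MR) sidesteps both problems
by using genotypes as instruments: alleles are assigned at conception,
before disease and independently of lifestyle, so a genotype that raises
25-OHD acts like a lifetime micro-randomization to higher vitamin D.

`vitdmr` implements this analysis for a case-control design with four
vitamin-D-pathway SNPs — rs2282679 (*GC*), rs12785878 (*DHCR7*), rs10741657
(*CYP2R1*), rs6013897 (*CYP24A1*) — and the three unweighted allele scores
built from them (overall; "upstream"/synthesis: rs12785878 + rs10741657;
"downstream"/metabolism: rs2282679 + rs6013897).

## The model

Write $Y$ for case status, $X$ for plasma 25-OHD in ng/ml (month-standardized),
$Z$ for an instrument (a 0/1/2 raising-allele count or a $0..2k$ allele
score), $U$ for unmeasured confounding. The instrument assumptions are the
usual three: $Z$ is associated with $X$; $Z$ is independent of $U$; and $Z$
affects $Y$ only through $X$ (no pleiotropy).

The package's primary estimator is the **control function** (two-stage
residual inclusion):

1. first stage, OLS: $X = \gamma_0 + \gamma_1 Z + C'\gamma + v$, giving
   fitted values $\hat X$ and residuals $\hat v$;
2. second stage, logistic ML:
   $\operatorname{logit} P(Y = 1) = \alpha + \psi \hat X + \rho \hat v + C'\beta$.

The residual term $\hat v$ carries whatever part of $X$ is correlated with
$U$; conditioning on it purges the confounded variation, and
$\exp(\psi)$ is reported as the causal odds ratio per ng/ml. Four companion
estimators are provided for triangulation:

* **Wald ratio**: $\hat\psi = \hat\beta_{ZY} / \hat\gamma_{ZX}$, the
  instrument-outcome logistic coefficient over the instrument-exposure
  linear coefficient;
* **two-stage**: the second stage without the residual term;
* **multiplicative structural mean model (MSMM)**: G-estimation solving
  $\sum_i (Z_i - \bar Z)\, Y_i\, e^{-\psi X_i} = 0$; its $\exp(\psi)$ is a
  risk-ratio-scale parameter and is labelled as such;
* **logistic structural mean model (LSMM)**: an ML association model
  $\operatorname{logit} P(Y\mid Z, X)$ followed by G-estimation of
  $\sum_i (Z_i - \bar Z)\,\operatorname{expit}\!\big(\widehat{\operatorname{logit}}
  P(Y\mid Z_i, X_i) - \psi X_i\big) = 0$.

Instrument strength is summarized by the first-stage partial F statistic,
with $F < 10$ flagged as weak by the usual convention. Covariates (age and
sex in the standard adjusted analysis) enter both stages identically.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| deficiency threshold | 10 | ng/ml | the clinical binary split used throughout |
| quintile rule | pooled 20/40/60/80 percentiles, linear interpolation, left-closed | — | reproduces the published quintile bounds on matching data |
| weak-instrument flag | F < 10 | — | standard first-stage rule of thumb |
| bootstrap | 2,000 resamples, percentile | — | valid for all two-step estimators; the original analysis does not state its CI method |
| SMM root search | bracket ±2, expansion, tol 1e-8 | log-OR per ng/ml | ±2 per ng/ml is far beyond any plausible effect |
| effect scale | per 1 ng/ml | — | per-SD rescaling available via `scale =` |
| first stage sample | full case-control sample | — | mirrors the original analysis; `controls_only = TRUE` available because retrospective ascertainment can distort a full-sample first stage |

Two choices deserve comment. *Wald-type CIs* are used in all observational
association tables because the published intervals are symmetric on the log
scale. *Complete-case analysis* is used for every adjusted model, mirroring
the shrinking denominators of the published tables; every result row carries
its own n.

## The synthetic cohort generator

No subject-level data are distributed with the study this design follows,
so the package ships a generator (`sim_config()`, `generate_cohort()`)
whose defaults encode the study conditions:

* Hardy-Weinberg genotypes at allele frequencies estimated from the
  published all-sample genotype counts (A of rs2282679: 0.710; T of
  rs12785878: 0.811; A of rs10741657: 0.402; T of rs6013897: 0.810). These
  are approximations — the population frequencies are not printed.
* Per-allele effects on 25-OHD of 0.76, 0.81, 0.58 and 0.22 ng/ml,
  calibrated so the single-SNP first-stage F statistics at ~4,200 phenotyped
  subjects match the published adjusted instrument strengths (15.8, 13.5,
  10.9, 1.0) with residual SD 8 ng/ml.
* A sinusoidal month effect with amplitude 5 ng/ml (~40% of the 12.5 ng/ml
  baseline), peaking in late summer — the seasonality that month
  standardization removes.
* A standard-normal latent confounder $U$, additive on the phenotype
  (ng/ml) and on the disease log-odds. The default is a *confounded null*:
  no causal effect ($\psi = 0$) with $\gamma_{ux} = -3$,
  $\gamma_{uy} = 0.75$, which reproduces a protective observational
  association of roughly OR 0.78 per SD of 25-OHD while all valid IV
  analyses should find OR 1 — the generator's account of how the published
  observational and MR findings can coexist.
* Retrospective case-control ascertainment (2,001 cases, 2,237 controls by
  default) from a large prospective population, mirroring the study design
  and exposing ascertainment effects on the first stage.

What the generator does **not** emulate: the Gaussian phenotype is an
idealization (real 25-OHD is non-negative and right-skewed, so a small
fraction of simulated values can be negative under wide-SD settings);
genotypes are simulated without linkage disequilibrium; covariates are
independent of genotype and disease by construction; and missingness, when
requested, is MCAR. Passing tests therefore demonstrate the estimators'
statistical behaviour under the assumed causal structure, not robustness to
distributional quirks of real measurements.

## Numerical choices

* Month standardization subtracts empirical month means and restores the
  grand mean; it is idempotent, and strata with fewer than two observations
  are left uncentered with a warning. Because centering is empirical, the
  post-standardization between-month ANOVA F collapses to ~0 (monthly means
  are equalized exactly), which the tests assert.
* SMM estimating functions are evaluated with the phenotype centered
  (roots unchanged, overflow avoided) and scanned on a grid before
  `uniroot` refinement; when several sign changes exist the root nearest
  zero is taken, and when none exists on the (expanded) bracket the model is
  reported as non-identified together with the endpoint values. Bootstrap
  resamples search a narrow bracket around the full-sample root.
* Logistic fits flag separation (non-convergence or |coef| > 15 with an
  exploding SE) and report affected coefficients as non-estimable rather
  than returning spurious intervals. Zero cells in 2×2 tables trigger the
  Haldane-Anscombe correction, recorded on the result.
* Quintile ties that collapse a boundary still yield labels within five
  categories, with group sizes reported in a warning.

## Power of the design

`power_simulation()` estimates power by full-pipeline simulation — each
replicate generates a cohort, standardizes the phenotype, rebuilds the
instrument and re-runs the chosen estimator — rather than by a closed-form
approximation, so the number reported reflects the estimator actually used.
`paper_design_config()` encodes the published design for this purpose:
2,001 cases / 2,237 controls, per-allele effects set so the overall allele
score has first-stage F ≈ 16 at that sample size, and a protective causal
effect equal to the strongest observational contrast (extreme-quintile
OR 0.47) expressed per phenotype SD (8 ng/ml), i.e. ψ = log(0.47)/8 per
ng/ml. The published effect-size scale is ambiguous (a continuous OR of
0.76 "per unit" is implausibly strong per ng/ml), so this choice is the
package's own reading; under it, simulated power of the Wald analysis is
about 0.2 — an underpowered design, in qualitative agreement with the
original report of power ≈ 0.35. In the ascertained case-control sample the
realized first-stage F runs somewhat above the population-calibrated 16
because sampling on disease status slightly inflates the
instrument-phenotype covariance.

```{r power, eval = FALSE}
power_simulation(paper_design_config(), estimator = "wald",
                 reps = 300, seed = 1)
```

## Problem sizes used by the test suite

The shipped tests run the full machinery at reduced scale: null-coverage
checks use 300 replicates of n = 10,000 with 48-resample bootstrap SEs;
confounding-correction checks use 31 replicates at n = 50,000 (point
estimates only); parameter recovery uses 120 replicates at n = 20,000; and
the power check uses 300 replicates of the published design. These sizes
were chosen to keep Monte-Carlo error comfortably inside the asserted
bands.

## Known limitations

* Estimates are reported per ng/ml by default; comparisons with analyses on
  other scales require explicit rescaling (`scale =`).
* The MSMM parameter is a risk ratio, not an odds ratio; the two coincide
  only for rare outcomes.
* Logistic-scale IV estimands are non-collapsible: even without
  confounding, marginal and conditional odds ratios differ, so recovery of
  a generating ψ is approximate at common outcome frequencies (the tests
  use rare-outcome designs and widened tolerances where this matters).
* No pleiotropy modelling is included: the generator can simulate
  exclusion-restriction violations (`pleiotropy =`) for robustness studies,
  but the estimators assume the restriction holds.
* G-estimation with covariates residualizes the instrument on the
  covariates; efficient covariate-adjusted SMMs are out of scope.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config()                       # confounded-null study conditions
coh <- generate_cohort(cfg, seed = 1)     # 2,001 cases / 2,237 controls
coh <- add_allele_scores(prepare_phenotype(coh))

first_stage(coh, "score_overall", covariates = c("age", "sex"))
mr_fit(coh, "score_overall", covariates = c("age", "sex"),
       method = "control_function", boot = 500, seed = 1)
run_mr_grid(coh, methods = "control_function", seed = 1)
```
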