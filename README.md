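# vitdmr

Mendelian-randomization analysis of plasma 25-hydroxy-vitamin D (25-OHD)
and colorectal cancer (CRC) risk, for epidemiologists who want the full
causal pipeline — observational association models, genetic-instrument
construction, instrumental-variable (IV) estimation, weak-instrument
diagnostics and design power — as tested, reusable R functions.

Observationally, low plasma 25-OHD is associated with higher CRC risk, but
confounding and reverse causation make the association hard to interpret.
MR uses genotypes as instruments: with Y case status, X plasma 25-OHD
(ng/ml, month-standardized), Z a raising-allele count or allele score and C
covariates, the package's primary estimator is the control function
(two-stage residual inclusion):

    first stage:   X = γ₀ + γ₁ Z + C'γ + v            (OLS)
    second stage:  logit P(Y=1) = α + ψ X̂ + ρ v̂ + C'β (logistic ML)

with exp(ψ) the causal odds ratio per ng/ml and the first-stage partial F
(< 10 = weak) attached to every estimate. Four companion estimators —
Wald ratio, two-stage, and multiplicative / logistic structural mean models
by G-estimation — support triangulation. Instruments are the four
vitamin-D-pathway SNPs rs2282679 (*GC*), rs12785878 (*DHCR7*), rs10741657
(*CYP2R1*) and rs6013897 (*CYP24A1*) plus the overall, upstream-synthesis
and downstream-metabolism allele scores built from them.

Because no subject-level data are distributed, a synthetic case-control
generator with a known causal structure (Hardy-Weinberg genotypes,
seasonal phenotype variation, a latent confounder, retrospective
ascertainment) backs every stage; its defaults encode a *confounded null*
in which the observational association is protective while the true causal
effect is absent.

## Worked example

```r
library(vitdmr)

cfg <- sim_config()                         # confounded-null study conditions
coh <- generate_cohort(cfg, seed = 1)       # 2,001 cases / 2,237 controls
coh <- add_allele_scores(prepare_phenotype(coh))

# observational association (naive logistic, per ng/ml)
fit_logistic(y ~ x_std, data = coh)$coefficients[2, c("or", "ci_low", "ci_high")]
#>        or    ci_low   ci_high
#> 0.9738304 0.9668534 0.9808578

first_stage(coh, "score_overall", covariates = c("age", "sex"))
#> First-stage regression of x_std on score_overall (n = 4238)
#>   partial F = 21.07 on 1 and 4234 df; incremental R2 = 0.0049

mr_fit(coh, "score_overall", covariates = c("age", "sex"),
       method = "control_function", boot = 500, seed = 1)
#> Mendelian randomization: control_function estimator
#>   instrument score_overall (first-stage F = 21.07), age+sex, n = 4238
#>   causal odds ratio per ng/ml: 0.93 (95% CI 0.82, 1.03) [bootstrap]
```

The naive model shows a clearly protective observational association
(OR 0.974 per ng/ml ≈ 0.81 per 8 ng/ml SD, CI excluding 1) that is entirely
confounder-induced in this simulation; the control-function IV interval
covers 1, the true causal null. `run_mr_grid()` expands this to the full
instrument-by-adjustment grid, `balance_table()` checks
instrument-confounder independence, `power_simulation()` estimates design
power by full-pipeline simulation, and `run_pipeline()` orchestrates
everything (there is a thin CLI in `inst/scripts/vitdmr-cli.R`). The
methods vignette (`vignettes/mendelian-randomization-vitamin-d.Rmd`)
documents the models, defaults and numerical choices.

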