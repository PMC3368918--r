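Package: vitdmr
Title: Mendelian Randomization of Plasma Vitamin D and Colorectal Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrumental-variable (Mendelian randomization) analysis of the
    causal effect of plasma 25-hydroxy-vitamin D on colorectal cancer risk in
    a case-control design. Provides a synthetic case-control cohort generator
    with a known causal structure (Hardy-Weinberg genotypes, seasonal
    phenotype variation, latent confounding), month-standardization and
    quintile preparation of the phenotype, genotype quality control and
    allele-score instrument construction, observational logistic association
    models, five instrumental-variable estimators of the causal odds ratio
    (control function, Wald ratio, two-stage, multiplicative and logistic
    structural mean models) with weak-instrument F diagnostics, confounder
    balance tables, and simulation-based power estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
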