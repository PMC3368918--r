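test_that("partial F equals the squared t statistic for a single instrument", {
  coh <- null_population(n = 3000, seed = 101)
  for (covs in list(NULL, c("age", "sex"))) {
    fs <- first_stage(coh, "g_rs2282679", covariates = covs)
    rhs <- paste(c(covs, "g_rs2282679"), collapse = " + ")
    lmfit <- lm(reformulate(rhs, "x_std"), data = coh)
    tval <- summary(lmfit)$coefficients["g_rs2282679", "t value"]
    expect_equal(fs$partial_F, tval^2, tolerance = 1e-8)
  }
})

test_that("a null instrument yields F with mean near 1 and weak flag below 10", {
  set.seed(19)
  fstats <- vapply(1:200, function(r) {
    n <- 500
    d <- data.frame(y = rbinom(n, 1, 0.5), x_std = rnorm(n, 12, 8),
                    z = rbinom(n, 2, 0.4))
    first_stage(d, "z")$partial_F
  }, numeric(1))
  expect_equal(mean(fstats), 1, tolerance = 0.3)

  d <- data.frame(y = rbinom(300, 1, 0.5), x_std = rnorm(300, 12, 8),
                  z = rbinom(300, 2, 0.4))
  fs <- first_stage(d, "z")
  expect_identical(fs$weak, fs$partial_F < 10)

  d$z2 <- 1L
  expect_error(first_stage(d, "z2"), "constant instrument")
})

test_that("first-stage residuals sum to zero and the fit drops incomplete cases", {
  coh <- null_population(n = 1000, seed = 103)
  coh$x_std[1:20] <- NA
  fs <- first_stage(coh, "score_overall")
  expect_equal(sum(fs$residuals), 0, tolerance = 1e-8)
  expect_equal(fs$n, 980)
  expect_equal(fs$n_dropped, 20)
})

test_that("Wald ratio and two-stage estimates coincide for a binary instrument", {
  coh <- null_population(n = 4000, seed = 107)
  coh$z_bin <- as.integer(coh$g_rs2282679 >= 1)   # dominant coding: 2 levels
  for (covs in list(NULL, c("age", "sex"))) {
    w <- mr_fit(coh, "z_bin", covariates = covs, method = "wald",
                ci_method = "none")
    ts <- mr_fit(coh, "z_bin", covariates = covs, method = "two_stage",
                 ci_method = "none")
    expect_equal(w$psi, ts$psi, tolerance = 1e-8)
  }
})

test_that("a zero instrument-outcome association gives a Wald OR of 1", {
  # outcome engineered orthogonal to the instrument: numerator exactly 0
  z <- rep(0:2, each = 40)
  y <- rep(rep(0:1, each = 20), 3)
  x <- 10 + 2 * z + rep(seq(-2, 2, length.out = 40), 3)
  d <- data.frame(y = y, x_std = x, z = z)
  w <- mr_fit(d, "z", method = "wald", ci_method = "delta")
  expect_equal(w$or, 1, tolerance = 1e-10)

  # degenerate first stage (identical phenotype distribution at every
  # instrument level -> slope exactly 0) is refused, citing weakness
  d$x2 <- rep(seq(-2, 2, length.out = 40), 3)
  expect_error(mr_fit(d, "z", exposure = "x2", method = "wald",
                      ci_method = "none"),
               "unstable|weak")
})

test_that("the control function reduces to two-stage when there is no endogeneity", {
  coh <- null_population(n = 20000, seed = 109)
  cf <- mr_fit(coh, "score_overall", method = "control_function",
               ci_method = "none")
  ts <- mr_fit(coh, "score_overall", method = "two_stage", ci_method = "none")
  # residual coefficient is ~0 under no confounding, so the two nearly agree
  expect_lt(abs(cf$resid_coef), 0.01)
  expect_equal(cf$psi, ts$psi, tolerance = 0.01)
})

test_that("control-function vs two-stage divergence shrinks as confounding vanishes", {
  gaps <- vapply(c(1.2, 0.6, 0), function(guy) {
    diffs <- vapply(1:20, function(r) {
      coh <- null_population(n = 8000, seed = 7000 + r, gamma_u_x = 2,
                             gamma_u_y = guy)
      cf <- mr_fit(coh, "score_overall", method = "control_function",
                   ci_method = "none")$psi
      ts <- mr_fit(coh, "score_overall", method = "two_stage",
                   ci_method = "none")$psi
      abs(cf - ts)
    }, numeric(1))
    mean(diffs)
  }, numeric(1))
  expect_gt(gaps[1], gaps[3])
  expect_gt(gaps[2], gaps[3])
})

test_that("structural mean model roots match a dense grid-search oracle", {
  coh <- null_population(n = 4000, seed = 113, psi = -0.04,
                         alpha0 = qlogis(0.2))
  dm <- vitdmr:::.design(coh, "x_std", "y", "score_overall", NULL)

  # msmm oracle
  zc <- dm$Z[, 1] - mean(dm$Z[, 1])
  xc <- dm$x - mean(dm$x)
  g_msmm <- function(p) sum(zc * dm$y * exp(-p * xc))
  psi_m <- mr_fit(coh, "score_overall", method = "msmm", ci_method = "none")$psi
  expect_equal(psi_m, grid_root_oracle(g_msmm, psi_m - 0.1, psi_m + 0.1),
               tolerance = 1e-6)
  expect_equal(g_msmm(psi_m), 0, tolerance = 1e-6 * sum(abs(zc * dm$y)))

  # lsmm oracle: same association model, dense grid on the G-estimation step
  afit <- glm(dm$y ~ dm$Z[, 1] + dm$x, family = binomial())
  lp <- predict(afit)   # link scale
  g_lsmm <- function(p) sum(zc * plogis(lp - p * dm$x))
  psi_l <- mr_fit(coh, "score_overall", method = "lsmm", ci_method = "none")$psi
  expect_equal(psi_l, grid_root_oracle(g_lsmm, psi_l - 0.1, psi_l + 0.1),
               tolerance = 1e-6)
})

test_that("psi = 0 is the SMM root when the outcome is balanced within instrument levels", {
  # engineered orthogonality: equal case fractions at every instrument level
  z <- rep(0:2, each = 60)
  y <- rep(rep(0:1, each = 30), 3)
  x <- 12 + 1.5 * z + rep(seq(-4, 4, length.out = 60), 3)
  d <- data.frame(y = y, x_std = x, z = z)
  zc <- z - mean(z)
  expect_equal(sum(zc * y), 0)   # estimating function at psi = 0
  fit <- mr_fit(d, "z", method = "msmm", ci_method = "none")
  expect_equal(fit$psi, 0, tolerance = 1e-6)
})

test_that("msmm recovers the causal parameter under its own log-linear DGP", {
  psi_true <- -0.04
  set.seed(29)
  est <- vapply(1:100, function(r) {
    n <- 20000
    z <- rbinom(n, 2, 0.5)
    x <- 10 + 2 * z + rnorm(n, 0, 4)
    p <- pmin(exp(-2.5 + psi_true * x), 1)   # log-linear risk model
    y <- rbinom(n, 1, p)
    d <- data.frame(y = y, x_std = x, z = z)
    mr_fit(d, "z", method = "msmm", ci_method = "none")$psi
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - psi_true), 2 * mc_se + 1e-4)
})

test_that("non-identified structural mean models fail loudly with endpoint values", {
  # tiny, weak-instrument data: the estimating function has no root
  set.seed(31)
  n <- 120
  d <- data.frame(y = rbinom(n, 1, 0.5), x_std = rnorm(n, 12, 8),
                  z = rbinom(n, 2, 0.5))
  err <- tryCatch(mr_fit(d, "z", method = "msmm", ci_method = "none"),
                  error = function(e) conditionMessage(e))
  fit_or_msg <- err
  # either a root exists (fine) or the failure reports the endpoints
  if (is.character(fit_or_msg))
    expect_match(fit_or_msg, "no sign change.*g\\(lo\\)")
  else succeed()
})

test_that("bootstrap confidence intervals are reproducible bit-for-bit under a seed", {
  coh <- null_population(n = 2000, seed = 127)
  a <- mr_fit(coh, "score_overall", method = "control_function", boot = 50,
              seed = 99)
  b <- mr_fit(coh, "score_overall", method = "control_function", boot = 50,
              seed = 99)
  expect_identical(a$ci_psi, b$ci_psi)
  expect_identical(a$boot_psi, b$boot_psi)
})

test_that("the estimate grid has the full instrument-by-adjustment shape and isolates failures", {
  cfg <- sim_config(n_population = 30000, n_cases = 700, n_controls = 800)
  coh <- add_allele_scores(prepare_phenotype(generate_cohort(cfg, seed = 131)))
  grid <- run_mr_grid(coh, methods = "control_function", boot = 30, seed = 5)
  expect_s3_class(grid, "mr_grid")
  expect_equal(nrow(grid), 7 * 2)
  expect_setequal(unique(grid$adjustment), c("unadjusted", "age+sex"))
  expect_true(all(is.finite(grid$or) | nzchar(grid$note)))

  # determinism given the seed
  grid2 <- run_mr_grid(coh, methods = "control_function", boot = 30, seed = 5)
  expect_identical(grid$or, grid2$or)
  expect_identical(grid$ci_low, grid2$ci_low)

  # an estimator failure in one cell leaves the others populated
  coh$g_rs6013897 <- 0L   # constant instrument: that cell must fail
  grid3 <- run_mr_grid(coh, methods = "control_function", boot = 20, seed = 5)
  bad <- grid3$instrument == "rs6013897" & grid3$adjustment == "unadjusted"
  expect_match(grid3$note[bad], "constant|missing|not found|score")
  expect_true(any(is.finite(grid3$or[grid3$instrument == "rs2282679"])))
})

test_that("stronger instruments give narrower bootstrap intervals", {
  set.seed(37)
  narrower <- vapply(1:60, function(r) {
    widths <- vapply(c(0.4, 1.2), function(b) {
      specs <- default_snp_specs()
      for (i in seq_along(specs)) specs[[i]]$beta_x <- b
      cfg <- sim_config(n_population = 2500, n_cases = 0, n_controls = 0,
                        snps = specs, gamma_u_x = 0, gamma_u_y = 0,
                        alpha0 = 0, month_effects = rep(0, 12))
      coh <- add_allele_scores(prepare_phenotype(
        generate_cohort(cfg, seed = 8000 + r, ascertain = FALSE)))
      fit <- mr_fit(coh, "score_overall", method = "two_stage", boot = 40,
                    boot_type = "normal", seed = r)
      diff(fit$ci_psi)
    }, numeric(1))
    widths[2] < widths[1]
  }, logical(1))
  expect_gte(mean(narrower), 0.8)
})
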