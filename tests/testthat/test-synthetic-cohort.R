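test_that("genotype generation follows Binomial(2, p) and handles edge frequencies", {
  g <- generate_genotypes(5000, 0.5, seed = 1)
  expect_true(all(g %in% 0:2))
  expect_equal(mean(g), 1, tolerance = 0.05)

  expect_identical(generate_genotypes(50, 0, seed = 2), rep(0L, 50))
  expect_identical(generate_genotypes(50, 1, seed = 2), rep(2L, 50))
  expect_error(generate_genotypes(10, 1.2), "frequency")
  expect_error(generate_genotypes(10, -0.1), "frequency")

  # marginal distribution matches Binomial(2, p) by chi-square GOF at n = 1e5
  set.seed(7)
  g <- generate_genotypes(1e5, 0.287)
  obs <- tabulate(g + 1L, 3L)
  expected <- 1e5 * stats::dbinom(0:2, 2, 0.287)
  gof <- sum((obs - expected)^2 / expected)
  expect_gt(stats::pchisq(gof, df = 2, lower.tail = FALSE), 0.001)
})

test_that("generated genotypes pass the HWE test at close to the nominal rate", {
  set.seed(11)
  reject <- vapply(1:100, function(r) {
    g <- generate_genotypes(1e5, 0.287)
    hwe_test(tabulate(g + 1L, 3L))$p.value < 0.05
  }, logical(1))
  expect_gte(mean(!reject), 0.94)
})

test_that("a fixed seed fixes the cohort bit-for-bit", {
  cfg <- sim_config(n_population = 2000, n_cases = 100, n_controls = 150,
                    alpha0 = stats::qlogis(0.12))
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$x_raw, c2$x_raw))
})

test_that("infeasible ascertainment fails with the available counts reported", {
  cfg <- sim_config(n_population = 500, n_cases = 400, n_controls = 100,
                    alpha0 = stats::qlogis(0.03))
  expect_error(generate_cohort(cfg, seed = 1), "infeasible ascertainment")
  expect_error(generate_cohort(cfg, seed = 1), "requested 400 / 100")
})

test_that("with no effects anywhere the outcome-phenotype log-OR is centred at 0", {
  set.seed(21)
  lors <- vapply(1:200, function(r) {
    coh <- null_population(n = 800, seed = 3000 + r)
    unname(coef(glm(y ~ x_std, binomial, data = coh))[2])
  }, numeric(1))
  expect_lt(abs(mean(lors)), 3 * sd(lors) / sqrt(length(lors)))
})

test_that("confounding induces bias in the naive regression, with the analytic sign", {
  # U raises both the phenotype and the disease risk -> positive naive slope
  coh <- null_population(n = 50000, seed = 5, gamma_u_x = 2, gamma_u_y = 0.5)
  fit <- summary(glm(y ~ x_std, binomial, data = coh))$coefficients
  expect_gt(fit["x_std", "Estimate"], 0)
  expect_gt(fit["x_std", "Estimate"], 3 * fit["x_std", "Std. Error"])
})

test_that("the first stage recovers the per-allele effects of the generating model", {
  specs <- default_snp_specs()
  betas <- vapply(specs, `[[`, numeric(1), "beta_x")
  set.seed(31)
  est <- t(vapply(1:200, function(r) {
    coh <- null_population(n = 1500, seed = 4000 + r)
    vapply(names(specs), function(s)
      unname(coef(lm(reformulate(paste0("g_", s), "x_std"), coh))[2]),
      numeric(1))
  }, numeric(length(specs))))
  for (j in seq_along(specs)) {
    mc_se <- sd(est[, j]) / sqrt(nrow(est))
    expect_lt(abs(mean(est[, j]) - betas[j]), 2 * mc_se + 1e-12,
              label = sprintf("beta recovery for %s", names(specs)[j]))
  }
})

test_that("cohort invariants hold and MCAR missingness is injected on request", {
  cfg <- sim_config(n_population = 3000, n_cases = 200, n_controls = 300,
                    alpha0 = stats::qlogis(0.15), missingness = 0.1)
  coh <- generate_cohort(cfg, seed = 9)
  expect_true(all(coh$y %in% 0:1))
  expect_true(all(coh$month %in% 1:12))
  gc <- genotype_columns(coh)
  expect_length(gc, 4)
  gvals <- unlist(coh[gc])
  expect_true(all(is.na(gvals) | gvals %in% 0:2))
  miss <- mean(is.na(coh$x_raw))
  expect_gt(miss, 0.04); expect_lt(miss, 0.20)
  expect_equal(sum(coh$y), 200)
})

test_that("pleiotropy is off by default but can be switched on", {
  cfg0 <- sim_config(n_population = 2000, n_cases = 100, n_controls = 100)
  expect_true(all(cfg0$pleiotropy == 0))
  cfg1 <- sim_config(n_population = 2000, n_cases = 100, n_controls = 100,
                     pleiotropy = c(rs2282679 = 0.3))
  expect_equal(unname(cfg1$pleiotropy["rs2282679"]), 0.3)
  expect_equal(unname(cfg1$pleiotropy["rs6013897"]), 0)
})
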