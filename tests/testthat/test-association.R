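test_that("contingency odds ratios reproduce the published crude estimates", {
  # sufficient (>= 10 ng/ml) vs deficient vitamin D status and CRC
  or1 <- contingency_or(c(1028, 1411, 973, 826))
  expect_equal(round(or1$estimate, 2), 0.62)
  # top vs bottom 25-OHD quintile
  expect_equal(round(contingency_or(c(320, 511, 486, 366))$estimate, 2), 0.47)
  # genotype-deficiency contrasts
  expect_equal(round(contingency_or(c(767, 1163, 133, 165))$estimate, 2), 0.82)
  expect_equal(round(contingency_or(c(698, 905, 133, 165))$estimate, 2), 0.96)
})

test_that("contingency OR is exact, symmetric, and handles zero cells", {
  expect_equal(contingency_or(c(10, 10, 10, 10))$estimate, 1)
  m <- matrix(c(30, 20, 15, 40), 2, byrow = TRUE)
  res <- contingency_or(m)
  expect_equal(res$estimate, (30 * 40) / (20 * 15))
  # Woolf CI brackets the estimate
  expect_lt(res$ci_low, res$estimate); expect_gt(res$ci_high, res$estimate)

  zc <- contingency_or(c(5, 0, 3, 7))
  expect_true(zc$corrected)
  expect_true(is.finite(zc$ci_high))
  expect_error(contingency_or(c(0, 0, 3, 7)), "zero margin")
})

test_that("contingency OR agrees with the logistic-regression coefficient to 1e-8", {
  tab <- c(37, 52, 18, 61)  # a, b, c, d
  d <- data.frame(exposed = c(1, 1, 0, 0), case = c(1, 0, 1, 0), n = tab)
  fit <- fit_logistic(case ~ exposed, data = d, weights = d$n)
  b <- fit$coefficients$estimate[fit$coefficients$term == "exposed"]
  expect_equal(exp(b), contingency_or(tab)$estimate, tolerance = 1e-8)
})

test_that("grouped per-allele fits reproduce the published per-allele ORs", {
  cts <- rs2282679_def_counts()
  expect_equal(round(per_allele_or(cts$events, cts$non_events)$estimate, 2), 0.88)
  cts <- rs12785878_def_counts()
  expect_equal(round(per_allele_or(cts$events, cts$non_events)$estimate, 2), 0.89)
})

test_that("fit_logistic is the ML optimum (profile grid oracle) and flags separation", {
  # balanced intercept-only: log-odds 0
  d <- data.frame(y = rep(0:1, 25))
  fit <- fit_logistic(y ~ 1, data = d)
  expect_equal(fit$coefficients$estimate[1], 0, tolerance = 1e-8)
  expect_equal(fit$coefficients$or[1], 1, tolerance = 1e-8)

  # grouped dose data: no slope on a 101-point profile grid beats the MLE
  cts <- rs2282679_def_counts()
  d <- data.frame(dose = 0:2, ev = cts$events, ne = cts$non_events)
  fit <- fit_logistic(cbind(ev, ne) ~ dose, data = d)
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * d$dose)
    sum(d$ev * log(p) + d$ne * log(1 - p))
  }
  b_hat <- fit$coefficients$estimate
  ll_hat <- ll(b_hat[1], b_hat[2])
  for (b1 in seq(b_hat[2] - 0.5, b_hat[2] + 0.5, length.out = 101)) {
    prof <- optimize(function(b0) ll(b0, b1), interval = b_hat[1] + c(-3, 3),
                     maximum = TRUE)$objective
    expect_lte(prof, ll_hat + 1e-8)
  }

  # complete separation detected
  ds <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(1, 2, 3, 10, 11, 12))
  fit <- fit_logistic(y ~ x, data = ds)
  expect_true(fit$separation)
  expect_true(any(is.na(fit$coefficients$ci_high)))

  # rank deficiency rejected
  dd <- data.frame(y = rep(0:1, 10), a = rep(1:2, 10))
  dd$b <- dd$a * 2
  expect_error(fit_logistic(y ~ a + b, data = dd), "rank deficient")
})

test_that("the quintile trend test is calibrated under the null and powered under a gradient", {
  set.seed(5)
  pvals <- vapply(1:500, function(r) {
    d <- data.frame(y = rbinom(400, 1, 0.5), quintile = sample(1:5, 400, TRUE))
    trend_test("y", "quintile", d)$p
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.03)
  expect_lte(mean(pvals < 0.05), 0.07)

  # strong monotone gradient at n = 4000
  set.seed(6)
  q <- sample(1:5, 4000, TRUE)
  y <- rbinom(4000, 1, plogis(-0.8 + 0.3 * q))
  expect_lt(trend_test("y", "quintile", data.frame(y = y, quintile = q))$p, 1e-6)

  expect_error(trend_test("y", "quintile",
                          data.frame(y = rbinom(50, 1, 0.5), quintile = rep(3, 50))),
               "fewer than 2")
})

test_that("stratified analysis is invariant for identical strata and localizes effects", {
  coh <- null_population(n = 1200, seed = 77)
  coh$x_std <- coh$x_std  # continuous exposure
  half <- coh[1:600, ]
  dup <- rbind(half, half)
  dup$grp <- factor(rep(c("A", "B"), each = 600))
  res <- stratified_analysis(dup, "grp")
  expect_equal(res$or[1], res$or[2], tolerance = 1e-10)

  # synthetic effect only in stratum A
  set.seed(8)
  n <- 4000
  x <- rnorm(n, 12, 5)
  grp <- factor(sample(c("A", "B"), n, TRUE))
  y <- rbinom(n, 1, plogis(ifelse(grp == "A", -0.08 * (x - 12), 0)))
  d <- data.frame(y = y, x_std = x, grp = grp)
  res <- stratified_analysis(d, "grp")
  expect_lt(res$or[res$stratum == "A"], 0.95)
  expect_lt(res$p[res$stratum == "A"], 0.001)
  expect_equal(res$or[res$stratum == "B"], 1, tolerance = 0.05)

  # small strata skipped with a warning
  d$grp2 <- d$grp
  d$grp2[1:10] <- NA
  dsmall <- d[c(1:40), ]
  dsmall$grp3 <- factor(c(rep("big", 35), rep("tiny", 5)))
  expect_warning(stratified_analysis(dsmall, "grp3", min_n = 10), "skipped")
})

test_that("case-only stratifiers contrast each case stratum against all controls", {
  cfg <- sim_config(n_population = 20000, n_cases = 500, n_controls = 600)
  coh <- prepare_phenotype(generate_cohort(cfg, seed = 12))
  res <- stratified_analysis(coh, "symptom_group")
  expect_setequal(res$stratum, c("none", "mild", "severe", "both"))
  expect_true(all(res$n_controls == sum(coh$y == 0)))
})

test_that("the interaction LRT is zero for nested equality and calibrated under the null", {
  # counts engineered so the stratum-specific ORs are identical:
  # interaction MLE is 0 and the LRT statistic vanishes
  d <- expand.grid(g = 0:1, x = 0:1, y = 0:1)
  d$n <- c(40, 20, 20, 10, 20, 10, 40, 20) * 3
  d <- d[rep(seq_len(nrow(d)), d$n), c("g", "x", "y")]
  lrt <- interaction_lrt(d, "g", exposure = "x")
  expect_equal(unname(lrt$statistic), 0, tolerance = 1e-8)

  set.seed(15)
  pvals <- vapply(1:500, function(r) {
    n <- 400
    g <- rbinom(n, 2, 0.5)
    x <- rnorm(n, 12, 4)
    y <- rbinom(n, 1, plogis(0.1 * g - 0.02 * x))
    interaction_lrt(data.frame(y = y, g_s = g, x_std = x), "g_s")$p.value
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.03)
  expect_lte(mean(pvals < 0.05), 0.07)

  # strong crossover interaction at n = 4000
  set.seed(16)
  n <- 4000
  g <- rbinom(n, 2, 0.5)
  x <- rnorm(n, 12, 4)
  y <- rbinom(n, 1, plogis(0.08 * (x - 12) * (g - 1)))
  expect_lt(interaction_lrt(data.frame(y = y, g_s = g, x_std = x), "g_s")$p.value,
            0.001)
})
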