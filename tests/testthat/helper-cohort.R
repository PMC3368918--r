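# Shared fixtures: small cohorts built in code.

# A cohort-style (non-ascertained) null population with strong instruments
# and no confounding; prevalence ~50% so logistic fits are well conditioned.
null_population <- function(n = 5000, seed = 1, psi = 0,
                            gamma_u_x = 0, gamma_u_y = 0,
                            alpha0 = 0, sigma_x = 8,
                            month_effects = rep(0, 12)) {
  cfg <- sim_config(n_population = n, n_cases = 0, n_controls = 0,
                    psi = psi, gamma_u_x = gamma_u_x, gamma_u_y = gamma_u_y,
                    alpha0 = alpha0, sigma_x = sigma_x,
                    month_effects = month_effects)
  coh <- generate_cohort(cfg, seed = seed, ascertain = FALSE)
  add_allele_scores(prepare_phenotype(coh))
}

# Published genotype-deficiency counts (Table-2-shaped fixtures).
rs2282679_def_counts <- function() {
  list(events = c(133, 698, 767), non_events = c(165, 905, 1163))
}
rs12785878_def_counts <- function() {
  list(events = c(72, 470, 980), non_events = c(66, 620, 1366))
}

# Brute-force HWE chi-square oracle: expected counts from the estimated
# allele frequency, summed (O - E)^2 / E over cells with E > 0.
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p_alt <- (2 * n2 + n1) / (2 * n)
  e <- n * c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2)
  o <- c(n0, n1, n2)
  sum(((o - e)^2 / e)[e > 0])
}

# Grid-search oracle for an SMM estimating function: finest sign change of
# g on an equally spaced grid, refined once by linear interpolation.
grid_root_oracle <- function(g, lo, hi, n_grid = 1e5) {
  ps <- seq(lo, hi, length.out = n_grid)
  gv <- vapply(ps, g, numeric(1))
  flips <- which(sign(gv[-length(gv)]) != sign(gv[-1]))
  stopifnot(length(flips) >= 1)
  i <- flips[which.min(pmin(abs(ps[flips]), abs(ps[flips + 1])))]
  # linear interpolation inside the bracketing cell
  ps[i] - gv[i] * (ps[i + 1] - ps[i]) / (gv[i + 1] - gv[i])
}
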