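#' Odds ratio from a 2x2 contingency table
#'
#' Cross-product odds ratio with a Woolf (log-scale) confidence interval.
#' The table is oriented with exposure in rows (index category first,
#' reference second) and outcome in columns (cases first, controls second),
#' so `OR = (a d) / (b c)` for `a` = exposed cases, `b` = exposed controls,
#' `c` = reference cases, `d` = reference controls. If any cell is zero the
#' Haldane-Anscombe correction (add 0.5 to every cell) is applied to the
#' estimate and interval, and the correction is recorded.
#'
#' @param table 2x2 numeric matrix as described, or a length-4 vector
#'   `c(a, b, c, d)`.
#' @param level Confidence level (default 0.95).
#' @return An object of class `"or_result"`: a list with `estimate`,
#'   `ci_low`, `ci_high`, `p` (two-sided Wald), the cell counts, and whether
#'   the zero-cell correction was used.
#' @examples
#' # protective association of sufficient (>= 10 ng/ml) vitamin D status
#' contingency_or(c(1028, 1411, 973, 826))
#' @export
contingency_or <- function(table, level = 0.95) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2L, 2L)))
    cells <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  } else {
    stopifnot(length(table) == 4L)
    cells <- as.numeric(table)
  }
  if (any(is.na(cells)) || any(cells < 0))
    stop("all four cells must be non-negative counts", call. = FALSE)
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
    stop("zero margin: odds ratio undefined", call. = FALSE)
  corrected <- any(cells == 0)
  w <- if (corrected) cells + 0.5 else cells
  log_or <- log(w[1]) + log(w[4]) - log(w[2]) - log(w[3])
  se <- sqrt(sum(1 / w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(estimate = exp(log_or),
         ci_low = exp(log_or - z * se),
         ci_high = exp(log_or + z * se),
         p = 2 * stats::pnorm(-abs(log_or / se)),
         log_or = log_or, se = se,
         n_cases = a + cc, n_controls = b + d,
         cells = cells, corrected = corrected,
         level = level, model_label = "crude"),
    class = "or_result"
  )
}

#' @export
print.or_result <- function(x, digits = 2, ...) {
  cat(sprintf("OR %.*f (%.0f%% CI %.*f, %.*f), p = %s%s\n",
              digits, x$estimate, 100 * x$level,
              digits, x$ci_low, digits, x$ci_high,
              format.pval(x$p, digits = 2),
              if (isTRUE(x$corrected)) "  [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Maximum-likelihood logistic regression with diagnostics
#'
#' Thin wrapper around [stats::glm()] for the package's association models.
#' Accepts a binary response, a two-column `cbind(events, non_events)`
#' grouped response, or count weights, and returns a coefficient table with
#' odds ratios, Wald confidence intervals and p-values. Complete separation
#' is detected (non-convergence or diverging coefficients) and flagged; the
#' affected coefficients are reported as non-estimable (`NA` interval).
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param weights Optional count weights (for grouped binary data).
#' @param level Confidence level.
#' @return An object of class `"logit_fit"`: list with `coefficients` (a
#'   data.frame: estimate, se, z, p, or, ci_low, ci_high), `deviance`,
#'   `null.deviance`, `logLik`, `n`, `separation`, and the underlying `glm`.
#' @export
fit_logistic <- function(formula, data, weights = NULL, level = 0.95) {
  data <- as.data.frame(data)
  data$.wts <- if (is.null(weights)) rep(1, nrow(data)) else weights
  fit <- suppressWarnings(
    stats::glm(formula, family = stats::binomial(), data = data,
               weights = .wts, na.action = stats::na.omit)
  )
  if (fit$rank < ncol(stats::model.matrix(fit)))
    stop("design matrix is rank deficient after complete-case filtering",
         call. = FALSE)
  resp <- stats::model.response(stats::model.frame(fit))
  n_obs <- if (is.matrix(resp)) sum(resp) else sum(fit$prior.weights)
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separation <- !fit$converged | any(abs(est) > 15 & se > 100)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ctab <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    z = unname(est / se),
    p = 2 * stats::pnorm(-abs(unname(est / se))),
    or = exp(unname(est)),
    ci_low = exp(unname(est - zq * se)),
    ci_high = exp(unname(est + zq * se)),
    stringsAsFactors = FALSE
  )
  if (separation) {
    bad <- abs(ctab$estimate) > 15 & ctab$se > 100
    ctab$or[bad] <- NA_real_
    ctab$ci_low[bad] <- NA_real_
    ctab$ci_high[bad] <- NA_real_
  }
  structure(
    list(coefficients = ctab,
         deviance = fit$deviance,
         null.deviance = fit$null.deviance,
         logLik = as.numeric(stats::logLik(fit)),
         n = n_obs,
         separation = separation,
         level = level,
         glm = fit),
    class = "logit_fit"
  )
}

#' @export
print.logit_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic regression (n = %g, deviance = %.2f%s)\n",
              x$n, x$deviance,
              if (x$separation) "; WARNING: possible separation" else ""))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Per-allele odds ratio from grouped genotype counts
#'
#' Fits a grouped maximum-likelihood logistic regression of event status on
#' allele count (0/1/2) — the per-allele (log-additive) trend model used for
#' genotype-phenotype and genotype-disease tables.
#'
#' @param events Events (e.g. vitamin-D-deficient subjects) at dose 0, 1, 2.
#' @param non_events Non-events at dose 0, 1, 2.
#' @param level Confidence level.
#' @return An `"or_result"` for the per-allele slope.
#' @examples
#' per_allele_or(c(133, 698, 767), c(165, 905, 1163))  # ~ 0.88 per allele
#' @export
per_allele_or <- function(events, non_events, level = 0.95) {
  stopifnot(length(events) == 3L, length(non_events) == 3L)
  d <- data.frame(dose = 0:2, ev = events, ne = non_events)
  fit <- fit_logistic(cbind(ev, ne) ~ dose, data = d, level = level)
  row <- fit$coefficients[fit$coefficients$term == "dose", ]
  structure(
    list(estimate = row$or, ci_low = row$ci_low, ci_high = row$ci_high,
         p = row$p, log_or = row$estimate, se = row$se,
         n_cases = sum(events), n_controls = sum(non_events),
         corrected = FALSE, level = level, model_label = "per-allele"),
    class = "or_result"
  )
}

#' Trend test across ordered categories
#'
#' Wald p-value for the linear-in-category score coefficient of a logistic
#' model of the outcome on the (numeric) category, optionally adjusted for
#' covariates — the "p trend" of quintile tables.
#'
#' @param outcome Name of the binary outcome column.
#' @param group Name of the ordinal group column (e.g. `"quintile"`).
#' @param data Data frame.
#' @param covariates Optional character vector of adjustment columns.
#' @return List with `p`, `estimate` (log-odds per category), `se` and `n`.
#' @export
trend_test <- function(outcome, group, data, covariates = NULL) {
  g <- as.numeric(data[[group]])
  keep <- stats::complete.cases(data[c(outcome, group, covariates)])
  if (length(unique(g[keep])) < 2L)
    stop("trend test undefined: fewer than 2 populated categories",
         call. = FALSE)
  d <- data[keep, , drop = FALSE]
  d$.score <- as.numeric(d[[group]])
  rhs <- paste(c(".score", covariates), collapse = " + ")
  fit <- fit_logistic(stats::as.formula(paste(outcome, "~", rhs)), data = d)
  row <- fit$coefficients[fit$coefficients$term == ".score", ]
  list(p = row$p, estimate = row$estimate, se = row$se, n = fit$n)
}

#' Stratified continuous-phenotype association
#'
#' Runs the continuous-exposure logistic model (outcome on month-standardized
#' 25-OHD) independently within each stratum of a grouping variable (sex,
#' AJCC stage, symptom group, or time between diagnosis and recruitment).
#' Strata smaller than `min_n` complete cases are skipped with a warning.
#' For case-only stratifiers (stage, symptoms, recruitment time) each
#' stratum's cases are contrasted against the full control series.
#'
#' @param cohort Prepared cohort (needs `x_std`).
#' @param by Name of the stratifying column.
#' @param exposure Exposure column (default `"x_std"`).
#' @param outcome Outcome column (default `"y"`).
#' @param covariates Optional adjustment columns.
#' @param min_n Minimum complete cases per stratum (default 30).
#' @return Data frame with one row per stratum: OR per unit exposure, CI, p,
#'   and counts.
#' @export
stratified_analysis <- function(cohort, by, exposure = "x_std",
                                outcome = "y", covariates = NULL,
                                min_n = 30) {
  stopifnot(by %in% names(cohort))
  strata <- cohort[[by]]
  case_only <- all(is.na(strata[cohort[[outcome]] == 0]))
  levs <- if (is.factor(strata)) levels(strata) else sort(unique(stats::na.omit(strata)))
  out <- list()
  for (lev in levs) {
    d <- if (case_only) {
      rbind(cohort[!is.na(strata) & strata == lev, , drop = FALSE],
            cohort[cohort[[outcome]] == 0, , drop = FALSE])
    } else {
      cohort[!is.na(strata) & strata == lev, , drop = FALSE]
    }
    keep <- stats::complete.cases(d[c(outcome, exposure, covariates)])
    d <- d[keep, , drop = FALSE]
    if (nrow(d) < min_n || length(unique(d[[outcome]])) < 2L) {
      warning(sprintf("stratum '%s' skipped (n = %d complete cases)",
                      lev, nrow(d)), call. = FALSE)
      next
    }
    rhs <- paste(c(exposure, covariates), collapse = " + ")
    fit <- fit_logistic(stats::as.formula(paste(outcome, "~", rhs)), data = d)
    row <- fit$coefficients[fit$coefficients$term == exposure, ]
    out[[length(out) + 1L]] <- data.frame(
      stratum = as.character(lev),
      or = row$or, ci_low = row$ci_low, ci_high = row$ci_high, p = row$p,
      n_cases = sum(d[[outcome]] == 1), n_controls = sum(d[[outcome]] == 0),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Genotype-by-phenotype interaction likelihood ratio test
#'
#' Compares nested logistic models of the outcome with and without the
#' genotype x phenotype product term(s) by a likelihood ratio test.
#'
#' @param cohort Prepared cohort.
#' @param snp SNP id (uses column `g_<snp>`) or any column name to interact.
#' @param exposure Phenotype column (default `"x_std"`).
#' @param outcome Outcome column.
#' @param covariates Optional adjustment columns.
#' @return An `"htest"` with the LRT `statistic`, df and `p.value`.
#' @export
interaction_lrt <- function(cohort, snp, exposure = "x_std", outcome = "y",
                            covariates = NULL) {
  col <- if (snp %in% names(cohort)) snp else paste0("g_", snp)
  stopifnot(col %in% names(cohort))
  keep <- stats::complete.cases(cohort[c(outcome, exposure, col, covariates)])
  d <- cohort[keep, , drop = FALSE]
  base <- paste(c(col, exposure, covariates), collapse = " + ")
  f0 <- stats::as.formula(paste(outcome, "~", base))
  f1 <- stats::as.formula(paste(outcome, "~", base, "+", col, ":", exposure))
  m0 <- stats::glm(f0, family = stats::binomial(), data = d)
  m1 <- stats::glm(f1, family = stats::binomial(), data = d)
  stat <- max(0, m0$deviance - m1$deviance)
  df <- m0$df.residual - m1$df.residual
  structure(
    list(statistic = c("LRT" = stat),
         parameter = c(df = df),
         p.value = stats::pchisq(stat, df = df, lower.tail = FALSE),
         method = "likelihood ratio test for genotype x phenotype interaction",
         data.name = sprintf("%s x %s on %s (n = %d)", col, exposure, outcome,
                             nrow(d))),
    class = "htest"
  )
}
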