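# Instrumental-variable estimators of the causal odds ratio.
#
# All estimators share a matrix-based internal path so the subject-level
# bootstrap and the simulation studies stay fast: design matrices are built
# once and estimators are re-run on resampled row indices.

# Fast logistic ML on a prebuilt design matrix. Returns coefficients (and
# optionally the dispersion-free covariance). glm.fit does the IRLS.
.logit_fit <- function(X, y, vcov = FALSE) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  out <- list(coef = fit$coefficients, converged = fit$converged,
              deviance = fit$deviance)
  if (vcov) {
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    out$vcov <- chol2inv(chol(XtWX))
  }
  out
}

.ols_fit <- function(X, yv) {
  fit <- stats::lm.fit(X, yv)
  list(coef = fit$coefficients, residuals = fit$residuals,
       fitted = fit$fitted.values, rank = fit$rank,
       rss = sum(fit$residuals^2))
}

# Build [intercept | covariates | instrument] matrices from a cohort.
.design <- function(data, exposure, outcome, instrument, covariates) {
  cols <- c(outcome, exposure, instrument, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  keep <- stats::complete.cases(data[cols])
  d <- data[keep, cols, drop = FALSE]
  y <- as.numeric(d[[outcome]])
  if (!all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  x <- as.numeric(d[[exposure]])
  Z <- as.matrix(vapply(instrument, function(cn) as.numeric(d[[cn]]),
                        numeric(nrow(d))))
  colnames(Z) <- instrument
  if (any(apply(Z, 2, stats::var) == 0))
    stop("constant instrument: no variation in ",
         paste(instrument[apply(Z, 2, stats::var) == 0], collapse = ", "),
         call. = FALSE)
  C <- if (length(covariates)) {
    stats::model.matrix(stats::as.formula(paste("~", paste(covariates, collapse = "+"))),
                        data = d)[, -1, drop = FALSE]
  } else {
    matrix(numeric(0), nrow = nrow(d), ncol = 0)
  }
  list(y = y, x = x, Z = Z, C = C, n = nrow(d), n_dropped = sum(!keep))
}

# First-stage OLS on index rows; returns fitted, residuals, partial F, R2.
.first_stage_idx <- function(dm, idx = NULL, controls_only = FALSE) {
  y <- dm$y; x <- dm$x; Z <- dm$Z; C <- dm$C
  if (!is.null(idx)) {
    y <- y[idx]; x <- x[idx]; Z <- Z[idx, , drop = FALSE]
    C <- C[idx, , drop = FALSE]
  }
  n <- length(x)
  W_red <- cbind(`(Intercept)` = rep(1, n), C)
  W_full <- cbind(W_red, Z)
  sub <- if (controls_only) which(y == 0) else seq_len(n)
  full <- .ols_fit(W_full[sub, , drop = FALSE], x[sub])
  red <- .ols_fit(W_red[sub, , drop = FALSE], x[sub])
  q <- ncol(Z)
  p <- ncol(W_full)
  df2 <- length(sub) - p
  partial_F <- ((red$rss - full$rss) / q) / (full$rss / df2)
  tss <- sum((x[sub] - mean(x[sub]))^2)
  fitted_all <- as.vector(W_full %*% full$coef)
  list(coef = full$coef, fitted = fitted_all, residuals = x - fitted_all,
       partial_F = partial_F, r2_instrument = (red$rss - full$rss) / tss,
       df = c(q, df2), n = n, n_first_stage = length(sub),
       sigma2 = full$rss / df2,
       W_red = W_red)
}

#' First-stage instrument model
#'
#' Ordinary least squares of the phenotype on the instrument(s) and
#' covariates, with the partial F statistic for the instrument block
#' (`F = ((RSS_reduced - RSS_full)/q) / (RSS_full/(n - p))`) and its
#' incremental R-squared. `F < 10` is conventionally taken as evidence of a
#' weak instrument and is flagged.
#'
#' @param data Cohort data frame.
#' @param instrument Column name(s) of the numeric instrument: a 0/1/2
#'   genotype or a 0..2k allele score.
#' @param exposure Phenotype column (default `"x_std"`).
#' @param covariates Optional covariate column names.
#' @param outcome Outcome column (used only for complete-case filtering and
#'   the controls-only option).
#' @param controls_only Fit the first stage on controls only (retrospective
#'   ascertainment can distort a first stage fitted on the full case-control
#'   sample); default `FALSE`, i.e. full sample.
#' @return Object of class `"first_stage_fit"`: coefficients, fitted values,
#'   residuals, `partial_F`, `r2_instrument`, degrees of freedom, `weak`
#'   flag.
#' @export
first_stage <- function(data, instrument, exposure = "x_std",
                        covariates = NULL, outcome = "y",
                        controls_only = FALSE) {
  dm <- .design(data, exposure, outcome, instrument, covariates)
  fs <- .first_stage_idx(dm, controls_only = controls_only)
  structure(
    list(coefficients = fs$coef,
         fitted = fs$fitted,
         residuals = fs$residuals,
         partial_F = fs$partial_F,
         r2_instrument = fs$r2_instrument,
         df = fs$df,
         n = fs$n,
         n_dropped = dm$n_dropped,
         weak = fs$partial_F < 10,
         instrument = instrument,
         exposure = exposure,
         covariates = covariates,
         controls_only = controls_only),
    class = "first_stage_fit"
  )
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat(sprintf("First-stage regression of %s on %s (n = %d%s)\n",
              x$exposure, paste(x$instrument, collapse = " + "), x$n,
              if (x$controls_only) ", controls only" else ""))
  cat(sprintf("  partial F = %.2f on %d and %d df; incremental R2 = %.4f%s\n",
              x$partial_F, x$df[1], x$df[2], x$r2_instrument,
              if (x$weak) "  [WEAK INSTRUMENT: F < 10]" else ""))
  invisible(x)
}

#' @export
residuals.first_stage_fit <- function(object, ...) object$residuals

# ---- point estimators (log-scale causal effect psi per ng/ml) -------------

.est_control_function <- function(dm, idx = NULL, controls_only = FALSE,
                                  keep_second = FALSE) {
  fs <- .first_stage_idx(dm, idx, controls_only)
  y <- if (is.null(idx)) dm$y else dm$y[idx]
  C <- if (is.null(idx)) dm$C else dm$C[idx, , drop = FALSE]
  X2 <- cbind(1, fs$fitted, fs$residuals, C)
  fit <- .logit_fit(X2, y, vcov = keep_second)
  if (!fit$converged || abs(fit$coef[2]) > 15)
    stop("second-stage logistic regression did not converge (separation?)",
         call. = FALSE)
  out <- list(psi = unname(fit$coef[2]), resid_coef = unname(fit$coef[3]),
              partial_F = fs$partial_F, fs = fs)
  if (keep_second) out$se <- sqrt(fit$vcov[2, 2])
  out
}

.est_two_stage <- function(dm, idx = NULL, controls_only = FALSE,
                           keep_second = FALSE) {
  fs <- .first_stage_idx(dm, idx, controls_only)
  y <- if (is.null(idx)) dm$y else dm$y[idx]
  C <- if (is.null(idx)) dm$C else dm$C[idx, , drop = FALSE]
  X2 <- cbind(1, fs$fitted, C)
  fit <- .logit_fit(X2, y, vcov = keep_second)
  if (!fit$converged || abs(fit$coef[2]) > 15)
    stop("second-stage logistic regression did not converge (separation?)",
         call. = FALSE)
  out <- list(psi = unname(fit$coef[2]), partial_F = fs$partial_F, fs = fs)
  if (keep_second) out$se <- sqrt(fit$vcov[2, 2])
  out
}

.est_wald <- function(dm, idx = NULL, controls_only = FALSE, delta = FALSE) {
  if (ncol(dm$Z) != 1L)
    stop("the Wald ratio estimator requires a single instrument column",
         call. = FALSE)
  fs <- .first_stage_idx(dm, idx, controls_only)
  y <- if (is.null(idx)) dm$y else dm$y[idx]
  Z <- if (is.null(idx)) dm$Z else dm$Z[idx, , drop = FALSE]
  C <- if (is.null(idx)) dm$C else dm$C[idx, , drop = FALSE]
  den <- unname(fs$coef[length(fs$coef)])  # instrument is the last column
  if (fs$partial_F < 1e-6 || abs(den) < .Machine$double.eps^0.5)
    stop(sprintf("first-stage coefficient is ~0 (partial F = %.3g): Wald ratio unstable; weak instrument",
                 fs$partial_F), call. = FALSE)
  Xr <- cbind(1, Z, C)
  num_fit <- .logit_fit(Xr, y, vcov = TRUE)
  num <- unname(num_fit$coef[2])
  psi <- num / den
  out <- list(psi = psi, num = num, den = den, partial_F = fs$partial_F,
              fs = fs)
  if (delta) {
    v_num <- num_fit$vcov[2, 2]
    # var(den) = den^2 / F for a single instrument (F = t^2 identity)
    v_den <- den^2 / fs$partial_F
    out$se <- sqrt(v_num / den^2 + num^2 * v_den / den^4)
  }
  out
}

# Structural-mean-model estimating functions. The instrument is centered on
# its covariate-predicted mean (plain mean when no covariates), and the
# phenotype is centered for numerical stability (roots are unchanged).
.smm_center_z <- function(dm, idx) {
  Z <- if (is.null(idx)) dm$Z else dm$Z[idx, , drop = FALSE]
  C <- if (is.null(idx)) dm$C else dm$C[idx, , drop = FALSE]
  z <- Z[, 1]
  if (ncol(dm$Z) != 1L)
    stop("structural mean models require a single instrument column",
         call. = FALSE)
  if (ncol(C)) {
    W <- cbind(1, C)
    z - as.vector(W %*% .ols_fit(W, z)$coef)
  } else {
    z - mean(z)
  }
}

.msmm_estfun <- function(psi, zc, y, xc) sum(zc * y * exp(-psi * xc))

.est_msmm <- function(dm, idx = NULL, bounds = c(-2, 2), tol = 1e-10,
                      grid_n = 81L) {
  y <- if (is.null(idx)) dm$y else dm$y[idx]
  x <- if (is.null(idx)) dm$x else dm$x[idx]
  zc <- .smm_center_z(dm, idx)
  xc <- x - mean(x)
  root <- .smm_root(function(p) .msmm_estfun(p, zc, y, xc), bounds, tol,
                    grid_n)
  list(psi = root)
}

.est_lsmm <- function(dm, idx = NULL, bounds = c(-2, 2), tol = 1e-10,
                      grid_n = 81L) {
  y <- if (is.null(idx)) dm$y else dm$y[idx]
  x <- if (is.null(idx)) dm$x else dm$x[idx]
  Z <- if (is.null(idx)) dm$Z else dm$Z[idx, , drop = FALSE]
  C <- if (is.null(idx)) dm$C else dm$C[idx, , drop = FALSE]
  zc <- .smm_center_z(dm, idx)
  # association model: ML logistic of Y on Z, X (and covariates)
  Xa <- cbind(1, Z, x, C)
  afit <- .logit_fit(Xa, y)
  if (!afit$converged || any(abs(afit$coef) > 15))
    stop("association-model logistic regression did not converge (separation?)",
         call. = FALSE)
  lp <- as.vector(Xa %*% afit$coef)
  root <- .smm_root(function(p) sum(zc * stats::plogis(lp - p * x)),
                    bounds, tol, grid_n)
  list(psi = root)
}

# Bracketed root with expansion-on-failure. The estimating function is
# scanned on a grid over the bracket (overflowed cells are skipped), the
# sign change nearest zero is refined by uniroot, and the bracket is doubled
# when no sign change is found; endpoint values are reported on failure.
.smm_root <- function(g, bounds, tol, grid_n = 81L) {
  lo <- bounds[1]; hi <- bounds[2]
  for (try in 0:3) {
    grid <- seq(lo, hi, length.out = grid_n)
    gv <- vapply(grid, g, numeric(1))
    ok <- is.finite(gv)
    exact <- which(ok & gv == 0)
    if (length(exact)) return(grid[exact[which.min(abs(grid[exact]))]])
    flips <- which(ok[-length(ok)] & ok[-1] &
                     sign(gv[-length(gv)]) != sign(gv[-1]))
    if (length(flips)) {
      i <- flips[which.min(pmin(abs(grid[flips]), abs(grid[flips + 1])))]
      return(stats::uniroot(g, c(grid[i], grid[i + 1]), tol = tol)$root)
    }
    lo <- 2 * lo; hi <- 2 * hi
  }
  stop(sprintf(
    "estimating function has no sign change on [%.1f, %.1f] (g(lo) = %.3g, g(hi) = %.3g): parameter not identified",
    lo, hi, g(lo), g(hi)), call. = FALSE)
}

.mr_methods <- c("control_function", "two_stage", "wald", "msmm", "lsmm")

.mr_point <- function(dm, method, idx = NULL, controls_only = FALSE,
                      psi_bounds = c(-2, 2)) {
  # resamples search a narrow bracket: a coarser scan grid suffices
  gn <- if (is.null(idx)) 81L else 33L
  switch(method,
         control_function = .est_control_function(dm, idx, controls_only)$psi,
         two_stage = .est_two_stage(dm, idx, controls_only)$psi,
         wald = .est_wald(dm, idx, controls_only)$psi,
         msmm = .est_msmm(dm, idx, bounds = psi_bounds, grid_n = gn)$psi,
         lsmm = .est_lsmm(dm, idx, bounds = psi_bounds, grid_n = gn)$psi)
}

#' Instrumental-variable estimate of the causal odds ratio
#'
#' Fits one of five instrumental-variable estimators of the causal effect of
#' the phenotype (plasma 25-OHD, ng/ml) on a binary outcome, using a genotype
#' or allele score as the instrument:
#'
#' * `"control_function"` (the primary method): first-stage OLS of the
#'   phenotype on the instrument, then a logistic regression of the outcome
#'   on the first-stage fitted values *and residuals* (two-stage residual
#'   inclusion); the residual term absorbs unmeasured phenotype-outcome
#'   confounding.
#' * `"two_stage"`: as above without the residual term.
#' * `"wald"`: ratio of the instrument-outcome logistic coefficient to the
#'   instrument-phenotype linear coefficient.
#' * `"msmm"`: multiplicative structural mean model by G-estimation — the
#'   root of \eqn{\sum_i (Z_i - \bar Z) Y_i e^{-\psi X_i} = 0}; `exp(psi)` is
#'   a risk-ratio-scale causal parameter and is labelled as such.
#' * `"lsmm"`: logistic structural mean model — an ML association model
#'   `logit P(Y|Z,X)` followed by G-estimation of the root of
#'   \eqn{\sum_i (Z_i - \bar Z)\,\mathrm{expit}(\widehat{logit}\,P(Y|Z_i,X_i) - \psi X_i) = 0};
#'   `exp(psi)` is an odds-ratio-scale causal parameter.
#'
#' The causal effect is reported per 1 ng/ml of 25-OHD by default; set
#' `scale` to a phenotype SD to report per-SD effects. Confidence intervals
#' are by nonparametric subject-level bootstrap re-running the whole
#' procedure (default), or by the delta method for the Wald ratio.
#'
#' @param data Cohort data frame.
#' @param instrument Instrument column name(s); the structural mean models
#'   and the Wald ratio require a single column.
#' @param exposure,outcome Phenotype and binary outcome column names.
#' @param covariates Optional covariate names; they enter both stages.
#' @param method Estimator; see above.
#' @param ci_method `"bootstrap"`, `"delta"` (Wald, and second-stage
#'   model-based for control_function/two_stage) or `"none"`.
#' @param boot Number of bootstrap resamples (default 2000).
#' @param boot_type `"percentile"` (default) or `"normal"` (estimate +/- z *
#'   bootstrap SE, cheaper at small `boot`).
#' @param level Confidence level.
#' @param seed Optional seed making the bootstrap reproducible bit-for-bit.
#' @param controls_only Fit the first stage on controls only.
#' @param psi_bounds Initial root-search bracket for the structural mean
#'   models (log scale per ng/ml), expanded on failure.
#' @param scale Report the effect per `scale` ng/ml (default 1).
#' @return Object of class `"mr_fit"` with the causal `or` (per `scale`
#'   ng/ml), its CI, the log-scale `psi` and bootstrap draws summary, the
#'   first-stage `f_stat`, and the effective `n`.
#' @seealso [first_stage()], [run_mr_grid()]
#' @export
mr_fit <- function(data, instrument, exposure = "x_std", outcome = "y",
                   covariates = NULL,
                   method = c("control_function", "two_stage", "wald",
                              "msmm", "lsmm"),
                   ci_method = NULL, boot = 2000,
                   boot_type = c("percentile", "normal"),
                   level = 0.95, seed = NULL, controls_only = FALSE,
                   psi_bounds = c(-2, 2), scale = 1) {
  method <- match.arg(method)
  boot_type <- match.arg(boot_type)
  if (is.null(ci_method)) ci_method <- if (method == "wald") "delta" else "bootstrap"
  ci_method <- match.arg(ci_method, c("bootstrap", "delta", "none"))
  dm <- .design(data, exposure, outcome, instrument, covariates)

  fs <- .first_stage_idx(dm, controls_only = controls_only)
  point <- switch(method,
    control_function = .est_control_function(dm, controls_only = controls_only,
                                             keep_second = TRUE),
    two_stage = .est_two_stage(dm, controls_only = controls_only,
                               keep_second = TRUE),
    wald = .est_wald(dm, controls_only = controls_only, delta = TRUE),
    msmm = .est_msmm(dm, bounds = psi_bounds),
    lsmm = .est_lsmm(dm, bounds = psi_bounds))
  psi <- point$psi

  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci_psi <- c(NA_real_, NA_real_)
  se <- point$se %||% NA_real_
  boot_psi <- NULL
  if (ci_method == "delta") {
    if (is.na(se))
      stop("delta-method CI not available for method '", method,
           "'; use ci_method = 'bootstrap'", call. = FALSE)
    ci_psi <- psi + c(-1, 1) * zq * se
  } else if (ci_method == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    n <- dm$n
    boot_psi <- rep(NA_real_, boot)
    # SMM resample roots cluster near the full-sample root: search a narrow
    # bracket first (the root finder expands it if needed)
    boot_bounds <- if (method %in% c("msmm", "lsmm"))
      psi + c(-0.5, 0.5) else psi_bounds
    for (b in seq_len(boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot_psi[b] <- tryCatch(
        .mr_point(dm, method, idx, controls_only, boot_bounds),
        error = function(e) NA_real_)
    }
    ok <- boot_psi[is.finite(boot_psi)]
    if (length(ok) < 0.5 * boot)
      stop(sprintf("bootstrap failed in %d of %d resamples; estimate not reliable",
                   boot - length(ok), boot), call. = FALSE)
    if (boot_type == "percentile") {
      ci_psi <- unname(stats::quantile(ok, c((1 - level) / 2, 1 - (1 - level) / 2),
                                       type = 7))
    } else {
      se <- stats::sd(ok)
      ci_psi <- psi + c(-1, 1) * zq * se
    }
    if (is.na(se)) se <- stats::sd(ok)
  }

  structure(
    list(method = method,
         psi = psi,
         or = exp(psi * scale),
         ci_low = exp(ci_psi[1] * scale),
         ci_high = exp(ci_psi[2] * scale),
         ci_psi = ci_psi,
         se = se,
         scale = scale,
         ci_method = ci_method,
         boot = if (ci_method == "bootstrap") boot else NA_integer_,
         boot_type = if (ci_method == "bootstrap") boot_type else NA_character_,
         boot_psi = boot_psi,
         f_stat = fs$partial_F,
         weak = fs$partial_F < 10,
         first_stage = list(coefficients = fs$coef, partial_F = fs$partial_F,
                            r2_instrument = fs$r2_instrument, df = fs$df,
                            fitted = fs$fitted, residuals = fs$residuals),
         resid_coef = point$resid_coef %||% NA_real_,
         instrument = paste(instrument, collapse = "+"),
         covariates = covariates,
         adjusted = if (length(covariates)) paste(covariates, collapse = "+") else "unadjusted",
         exposure = exposure, outcome = outcome,
         n = dm$n, n_dropped = dm$n_dropped,
         level = level, seed = seed,
         call = match.call()),
    class = "mr_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.effect_label <- function(method) {
  if (method == "msmm") "causal risk ratio" else "causal odds ratio"
}

#' @export
print.mr_fit <- function(x, digits = 2, ...) {
  cat(sprintf("Mendelian randomization: %s estimator\n", x$method))
  cat(sprintf("  instrument %s (first-stage F = %.2f%s), %s, n = %d\n",
              x$instrument, x$f_stat,
              if (x$weak) "; WEAK" else "", x$adjusted, x$n))
  unit <- if (x$scale == 1) "per ng/ml" else sprintf("per %g ng/ml", x$scale)
  cat(sprintf("  %s %s: %.*f (%.0f%% CI %.*f, %.*f) [%s]\n",
              .effect_label(x$method), unit,
              digits, x$or, 100 * x$level,
              digits, x$ci_low, digits, x$ci_high, x$ci_method))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(object, class = c("summary.mr_fit", class(object)))
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  print.mr_fit(x, digits = digits)
  cat(sprintf("  psi (log scale, per ng/ml): %.6f; SE %s\n", x$psi,
              if (is.na(x$se)) "n/a" else sprintf("%.6f", x$se)))
  cat(sprintf("  first-stage incremental R2: %.5f; complete cases used: %d (%d dropped)\n",
              x$first_stage$r2_instrument, x$n, x$n_dropped))
  if (!is.na(x$resid_coef))
    cat(sprintf("  control-function residual coefficient: %.5f\n", x$resid_coef))
  if (!is.null(x$boot_psi))
    cat(sprintf("  bootstrap: %d resamples (%s CI), %d failed\n",
                x$boot, x$boot_type, sum(!is.finite(x$boot_psi))))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  c(psi = object$psi, or = object$or)
}

#' @export
confint.mr_fit <- function(object, parm = "or", level = NULL, ...) {
  if (!is.null(level) && level != object$level)
    stop("refit with the desired 'level'; intervals are stored at level ",
         object$level, call. = FALSE)
  if (identical(parm, "psi")) {
    out <- matrix(object$ci_psi, nrow = 1,
                  dimnames = list("psi", c("lower", "upper")))
  } else {
    out <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
                  dimnames = list("or", c("lower", "upper")))
  }
  out
}

#' @export
residuals.mr_fit <- function(object, ...) object$first_stage$residuals

#' @export
plot.mr_fit <- function(x, ...) {
  if (!is.null(x$boot_psi) && any(is.finite(x$boot_psi))) {
    graphics::hist(exp(x$boot_psi[is.finite(x$boot_psi)] * x$scale),
                   breaks = 40, main = sprintf("%s bootstrap distribution", x$method),
                   xlab = .effect_label(x$method), ...)
    graphics::abline(v = x$or, lwd = 2)
    graphics::abline(v = 1, lty = 2)
  } else {
    graphics::plot(x$first_stage$fitted, x$first_stage$residuals,
                   xlab = "first-stage fitted phenotype (ng/ml)",
                   ylab = "first-stage residual", main = "First stage", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}

#' Full instrument-by-adjustment grid of IV estimates
#'
#' Runs an estimator over the full cross of instruments (by default the four
#' single SNPs and the three allele scores) and adjustment sets (by default
#' unadjusted and age + sex), reproducing the shape of the published
#' causal-odds-ratio table. Failures in one cell (e.g. non-identified
#' structural mean model) are reported in that row's `note` and do not stop
#' the rest of the grid.
#'
#' @param cohort Prepared cohort (with `x_std` and score columns; scores are
#'   added on the fly if absent).
#' @param methods Estimator name(s) passed to [mr_fit()].
#' @param instruments Named character vector/list of instrument columns;
#'   defaults to the 4 SNPs + 3 scores.
#' @param adjustments Named list of covariate sets; defaults to
#'   `list(unadjusted = NULL, "age+sex" = c("age","sex"))`.
#' @param boot,ci_method,seed,level Passed to [mr_fit()]; `boot` defaults to
#'   a lighter 500 resamples for the grid.
#' @param ... Further arguments to [mr_fit()].
#' @return A data frame of class `"mr_grid"`: one row per instrument x
#'   adjustment x method with `or`, `ci_low`, `ci_high`, `f_stat`, `n`,
#'   `note`.
#' @export
run_mr_grid <- function(cohort, methods = "control_function",
                        instruments = NULL, adjustments = NULL,
                        boot = 500, ci_method = NULL, seed = NULL,
                        level = 0.95, ...) {
  if (is.null(instruments)) {
    if (!all(paste0("score_", names(allele_score_components())) %in% names(cohort)))
      cohort <- add_allele_scores(cohort)
    instruments <- c(
      stats::setNames(genotype_columns(cohort), sub("^g_", "", genotype_columns(cohort))),
      score_overall = "score_overall",
      score_upstream = "score_upstream",
      score_downstream = "score_downstream")
  }
  if (is.null(adjustments))
    adjustments <- list(unadjusted = NULL, `age+sex` = c("age", "sex"))
  rows <- list()
  for (m in methods) for (ia in seq_along(instruments)) for (ja in seq_along(adjustments)) {
    inst <- instruments[[ia]]
    adj <- adjustments[[ja]]
    res <- tryCatch(
      mr_fit(cohort, instrument = inst, covariates = adj, method = m,
             boot = boot, ci_method = ci_method, seed = seed, level = level,
             ...),
      error = function(e) e)
    rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
      data.frame(instrument = names(instruments)[ia],
                 adjustment = names(adjustments)[ja], method = m,
                 or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 f_stat = NA_real_, n = NA_integer_,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(instrument = names(instruments)[ia],
                 adjustment = names(adjustments)[ja], method = m,
                 or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
                 f_stat = res$f_stat, n = res$n, note = "",
                 stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(instrument = character(0), adjustment = character(0),
                      method = character(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      f_stat = numeric(0), n = integer(0),
                      note = character(0))
  } else {
    out <- do.call(rbind, rows)
  }
  class(out) <- c("mr_grid", "data.frame")
  out
}

#' @export
print.mr_grid <- function(x, digits = 2, ...) {
  cat("Instrumental-variable causal odds ratio grid\n")
  fmt <- function(v) ifelse(is.na(v), "-", formatC(v, digits = digits, format = "f"))
  tab <- data.frame(instrument = x$instrument, adjustment = x$adjustment,
                    method = x$method,
                    OR = fmt(x$or),
                    `95% CI` = ifelse(is.na(x$or), "-",
                                      paste0(fmt(x$ci_low), ", ", fmt(x$ci_high))),
                    F = fmt(x$f_stat), n = x$n,
                    note = substr(x$note, 1, 40),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}
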