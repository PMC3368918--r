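#' Standardize a phenotype for month of blood draw
#'
#' Removes the seasonal month effect from plasma 25-OHD by centering each
#' month stratum on its own mean and adding back the grand mean, so that
#' monthly means of the standardized values are equal while the overall mean
#' is preserved. The operation is idempotent.
#'
#' @param x Numeric phenotype (ng/ml); may contain `NA`.
#' @param month Integer month of blood draw (1-12), same length as `x`;
#'   must be non-missing wherever `x` is observed.
#' @return Numeric vector of month-standardized values; `NA` where `x` is
#'   missing. A month stratum with fewer than 2 observations is left
#'   uncentered, with a warning.
#' @export
standardize_by_month <- function(x, month) {
  stopifnot(length(x) == length(month))
  obs <- !is.na(x)
  if (any(is.na(month[obs])))
    stop("'month' must be non-missing wherever the phenotype is observed",
         call. = FALSE)
  if (any(!(month[obs] %in% 1:12)))
    stop("'month' values must be in 1..12", call. = FALSE)
  out <- x
  grand <- mean(x[obs])
  counts <- tabulate(month[obs], nbins = 12L)
  small <- which(counts == 1L)
  if (length(small))
    warning(sprintf("month stratum with < 2 observations left uncentered: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
  mmeans <- rep(grand, 12L)
  ok <- counts >= 2L
  if (any(ok)) {
    mm <- tapply(x[obs], factor(month[obs], levels = 1:12), mean)
    mmeans[ok] <- mm[ok]
  }
  out[obs] <- x[obs] - mmeans[month[obs]] + grand
  out
}

#' Assign quintiles from the pooled distribution
#'
#' Quintile boundaries are the 20/40/60/80 empirical percentiles (linear
#' interpolation) of the pooled case + control distribution, or user-supplied
#' break points. Intervals are left-closed at each lower bound, and the lowest
#' quintile is open below, so a value exactly equal to a boundary falls in the
#' upper of the two adjacent quintiles.
#'
#' @param x Numeric vector (at least 5 non-missing values when `breaks` is
#'   `NULL`).
#' @param breaks Optional 4 interior boundaries, non-decreasing.
#' @return Integer vector of quintile labels 1-5 (`NA` preserved), with the
#'   interior boundaries attached as attribute `"breaks"`. If ties collapse a
#'   boundary, fewer than 5 groups are populated and a warning reports the
#'   group sizes.
#' @export
assign_quintiles <- function(x, breaks = NULL) {
  obs <- !is.na(x)
  if (is.null(breaks)) {
    if (sum(obs) < 5L)
      stop("need at least 5 non-missing values to form quintiles",
           call. = FALSE)
    breaks <- stats::quantile(x[obs], probs = c(0.2, 0.4, 0.6, 0.8),
                              names = FALSE, type = 7)
  }
  stopifnot(length(breaks) == 4L)
  if (is.unsorted(breaks))
    stop("'breaks' must be non-decreasing", call. = FALSE)
  q <- rep(NA_integer_, length(x))
  # left-closed on each lower bound: x >= break_k goes up
  q[obs] <- 1L + rowSums(outer(x[obs], breaks, `>=`))
  sizes <- tabulate(q[obs], nbins = 5L)
  if (any(sizes == 0L))
    warning(sprintf("degenerate quintiles; group sizes: %s",
                    paste(sizes, collapse = "/")), call. = FALSE)
  attr(q, "breaks") <- breaks
  q
}

#' Prepare the phenotype of a cohort for analysis
#'
#' Adds three columns to a cohort: `x_std`, the month-standardized 25-OHD;
#' `deficient`, the binary vitamin-D deficiency indicator at the clinical
#' threshold; and `quintile`, the pooled-distribution quintile of `x_std`.
#'
#' @param cohort A cohort data frame with columns `x_raw` and `month`.
#' @param threshold Deficiency threshold in ng/ml (default 10, i.e. < 10 ng/ml
#'   is deficient).
#' @param breaks Optional fixed quintile boundaries passed to
#'   [assign_quintiles()].
#' @return The cohort with `x_std`, `deficient` and `quintile` columns added.
#' @export
prepare_phenotype <- function(cohort, threshold = 10, breaks = NULL) {
  stopifnot(all(c("x_raw", "month") %in% names(cohort)))
  cohort$x_std <- standardize_by_month(cohort$x_raw, cohort$month)
  cohort$deficient <- as.integer(cohort$x_std < threshold)
  cohort$quintile <- assign_quintiles(cohort$x_std, breaks = breaks)
  cohort
}
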