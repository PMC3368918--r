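#' Hardy-Weinberg equilibrium chi-squared test
#'
#' Pearson 1-df chi-squared test of observed genotype counts against the
#' Hardy-Weinberg expectations `n * (p^2, 2pq, q^2)`, with the allele
#' frequency `p` estimated from the counts themselves. No continuity
#' correction is applied.
#'
#' @param counts Integer vector of length 3: counts of subjects with 0, 1 and
#'   2 copies of one allele (hom-ref, het, hom-alt). All counts must be
#'   non-negative and sum to a positive total.
#' @return An object of class `"htest"` with the chi-squared `statistic`
#'   (1 df), `p.value`, and the estimated allele frequency in `estimate`.
#' @examples
#' hwe_test(c(25, 50, 25))   # exact HWE: statistic 0, p = 1
#' @export
hwe_test <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0))
    stop("'counts' must be 3 non-negative genotype counts", call. = FALSE)
  n <- sum(counts)
  if (n <= 0) stop("total genotype count must be positive", call. = FALSE)
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  # cells with zero expectation contribute nothing (p = 0 or 1 exactly)
  use <- expected > 0
  stat <- sum((counts[use] - expected[use])^2 / expected[use])
  pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(
    list(statistic = c("X-squared" = stat),
         parameter = c(df = 1),
         p.value = pval,
         estimate = c("allele frequency" = p),
         method = "Hardy-Weinberg equilibrium chi-squared test",
         data.name = deparse(substitute(counts)),
         observed = counts, expected = expected),
    class = "htest"
  )
}

#' Default allele-score composition
#'
#' The three score definitions: `overall` combines all four SNPs, `upstream`
#' the two synthesis-pathway SNPs, `downstream` the two metabolism-pathway
#' SNPs.
#' @return Named list of SNP id vectors.
#' @export
allele_score_components <- function() {
  list(
    overall    = c("rs2282679", "rs12785878", "rs10741657", "rs6013897"),
    upstream   = c("rs12785878", "rs10741657"),
    downstream = c("rs2282679", "rs6013897")
  )
}

#' Build an allele-score instrument
#'
#' Unweighted sum of raising-allele counts across the component SNPs. All
#' component genotype columns must already be oriented as raising-allele
#' counts (0/1/2); a subject missing any component genotype gets a missing
#' score. An optional weighted variant multiplies each component by an
#' externally supplied per-allele weight.
#'
#' @param cohort Data frame with genotype columns named `g_<snp_id>`.
#' @param name `"overall"`, `"upstream"` or `"downstream"`, or any name when
#'   `components` is supplied directly.
#' @param components Optional character vector of SNP ids overriding the
#'   default composition.
#' @param weights Optional numeric per-SNP weights (same length and order as
#'   the components); default unweighted.
#' @return Numeric score vector (integer-valued when unweighted), range
#'   `0..2k` for `k` components, with attributes `"components"` and `"name"`.
#' @export
build_allele_score <- function(cohort, name = c("overall", "upstream", "downstream"),
                               components = NULL, weights = NULL) {
  if (is.null(components)) {
    name <- match.arg(name)
    components <- allele_score_components()[[name]]
  } else {
    name <- if (length(name) == 1L) name else "custom"
  }
  cols <- paste0("g_", components)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("genotype columns not found (are genotypes oriented and named g_<snp>?): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  G <- as.matrix(cohort[cols])
  bad <- G[!is.na(G)]
  if (any(bad < 0 | bad > 2))
    stop("genotype columns must contain raising-allele counts in {0,1,2}",
         call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(components))
  stopifnot(length(weights) == length(components))
  score <- as.vector(G %*% weights)  # NA propagates: missing component -> missing score
  attr(score, "components") <- components
  attr(score, "name") <- name
  score
}

#' Add the three standard allele scores to a cohort
#'
#' @param cohort Data frame with the four oriented genotype columns.
#' @return The cohort with `score_overall`, `score_upstream` and
#'   `score_downstream` columns added.
#' @export
add_allele_scores <- function(cohort) {
  for (nm in names(allele_score_components()))
    cohort[[paste0("score_", nm)]] <- build_allele_score(cohort, nm)
  cohort
}
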