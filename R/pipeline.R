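#' Ingest a subject-level cohort file
#'
#' Reads a CSV/TSV cohort table, validates it row by row, and returns an
#' analysis-ready cohort. Genotype columns `g_<snp>` may hold either 0/1/2
#' dosages (raising-allele counts) or allele-pair strings such as `"AC"`,
#' which are converted to raising-allele counts using the orientation in the
#' SNP specs. Rows with an unknown genotype symbol, an out-of-range month, or
#' a negative phenotype are rejected with a log line; a per-column
#' missingness report is attached.
#'
#' @param path CSV (default) or TSV file; the delimiter is chosen from the
#'   file extension.
#' @param snps Named list of [snp_spec()] giving allele orientation.
#' @param quiet Suppress per-row rejection messages.
#' @return An `mr_cohort` data frame; attributes `"missingness"` (per-column
#'   proportion) and `"rejected"` (row indices removed).
#' @export
ingest_cohort <- function(path, snps = default_snp_specs(), quiet = FALSE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("y", "x_raw", "month")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("input is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  gcols <- intersect(paste0("g_", names(snps)), names(raw))
  bad <- rep(FALSE, nrow(raw))
  note <- character(nrow(raw))

  # allele-pair strings -> raising-allele counts
  for (col in gcols) {
    spec <- snps[[sub("^g_", "", col)]]
    v <- raw[[col]]
    if (is.character(v)) {
      v2 <- rep(NA_integer_, length(v))
      pair <- !is.na(v)
      letters_ok <- grepl(sprintf("^[%s%s]{2}$", spec$raising_allele,
                                  spec$other_allele), v[pair])
      counts <- vapply(strsplit(v[pair], ""), function(a)
        sum(a == spec$raising_allele), integer(1))
      v2[pair][letters_ok] <- counts[letters_ok]
      unknown <- pair
      unknown[pair] <- !letters_ok
      bad <- bad | unknown
      note[unknown] <- paste0("unknown genotype symbol in ", col)
      raw[[col]] <- v2
    } else {
      out_of_range <- !is.na(v) & !(v %in% 0:2)
      bad <- bad | out_of_range
      note[out_of_range] <- paste0("genotype out of range in ", col)
    }
  }
  badm <- !is.na(raw$month) & !(raw$month %in% 1:12)
  note[badm] <- "month out of range"
  badx <- !is.na(raw$x_raw) & raw$x_raw < 0
  note[badx] <- "negative phenotype"
  bady <- !is.na(raw$y) & !(raw$y %in% 0:1)
  note[bady] <- "outcome not 0/1"
  bad <- bad | badm | badx | bady

  if (any(bad) && !quiet) {
    for (i in which(bad))
      message(sprintf("ingest: rejecting row %d (%s)", i, note[i]))
  }
  cohort <- raw[!bad, , drop = FALSE]
  for (col in c("smoking", "activity", "stage", "symptom_group", "tdr_group"))
    if (col %in% names(cohort) && is.character(cohort[[col]]))
      cohort[[col]] <- factor(cohort[[col]])
  if (!"id" %in% names(cohort)) cohort$id <- seq_len(nrow(cohort))
  attr(cohort, "snps") <- snps
  attr(cohort, "missingness") <- vapply(cohort, function(v) mean(is.na(v)),
                                        numeric(1))
  attr(cohort, "rejected") <- which(bad)
  class(cohort) <- c("mr_cohort", "data.frame")
  cohort
}

# Association tables in the shape of the published report -------------------

.table1 <- function(cohort, covariate_sets) {
  rows <- list()
  for (lab in names(covariate_sets)) {
    covs <- covariate_sets[[lab]]
    rhs <- paste(c("x_std", covs), collapse = " + ")
    fit <- fit_logistic(stats::as.formula(paste("y ~", rhs)), data = cohort)
    row <- fit$coefficients[fit$coefficients$term == "x_std", ]
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = "25-OHD continuous (per ng/ml)", model = lab,
      or = row$or, ci_low = row$ci_low, ci_high = row$ci_high, p = row$p,
      n = fit$n, stringsAsFactors = FALSE)
    # binary deficiency split (sufficient vs deficient reference)
    d <- cohort[stats::complete.cases(cohort[c("y", "deficient", covs)]), ]
    rhs_b <- paste(c("I(1 - deficient)", covs), collapse = " + ")
    fitb <- fit_logistic(stats::as.formula(paste("y ~", rhs_b)), data = d)
    rowb <- fitb$coefficients[2, ]
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = ">=10 vs <10 ng/ml", model = lab,
      or = rowb$or, ci_low = rowb$ci_low, ci_high = rowb$ci_high, p = rowb$p,
      n = fitb$n, stringsAsFactors = FALSE)
    # quintiles vs bottom
    dq <- cohort[stats::complete.cases(cohort[c("y", "quintile", covs)]), ]
    dq$quintile_f <- factor(dq$quintile, levels = 1:5)
    rhs_q <- paste(c("quintile_f", covs), collapse = " + ")
    fitq <- fit_logistic(stats::as.formula(paste("y ~", rhs_q)), data = dq)
    for (k in 2:5) {
      rq <- fitq$coefficients[fitq$coefficients$term == paste0("quintile_f", k), ]
      if (!nrow(rq)) next
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = sprintf("quintile %d vs 1", k), model = lab,
        or = rq$or, ci_low = rq$ci_low, ci_high = rq$ci_high, p = rq$p,
        n = fitq$n, stringsAsFactors = FALSE)
    }
    tt <- trend_test("y", "quintile", dq, covariates = covs)
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = "p trend across quintiles", model = lab,
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = tt$p,
      n = tt$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.genotype_table <- function(cohort, outcome) {
  rows <- list()
  for (col in genotype_columns(cohort)) {
    snp <- sub("^g_", "", col)
    d <- cohort[!is.na(cohort[[col]]) & !is.na(cohort[[outcome]]), ]
    counts <- table(factor(d[[col]], levels = 0:2), d[[outcome]])
    for (dose in 1:2) {
      m <- rbind(c(counts[dose + 1, "1"], counts[dose + 1, "0"]),
                 c(counts[1, "1"], counts[1, "0"]))
      res <- tryCatch(contingency_or(m), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        snp = snp, contrast = sprintf("%d vs 0 copies", dose),
        or = res$estimate %||% NA_real_,
        ci_low = res$ci_low %||% NA_real_, ci_high = res$ci_high %||% NA_real_,
        p = res$p %||% NA_real_,
        n = sum(m), stringsAsFactors = FALSE)
    }
    pa <- per_allele_or(counts[, "1"], counts[, "0"])
    rows[[length(rows) + 1L]] <- data.frame(
      snp = snp, contrast = "per raising allele",
      or = pa$estimate, ci_low = pa$ci_low, ci_high = pa$ci_high, p = pa$p,
      n = sum(counts), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.hwe_table <- function(cohort) {
  rows <- lapply(genotype_columns(cohort), function(col) {
    g <- cohort[[col]][!is.na(cohort[[col]])]
    ht <- hwe_test(tabulate(g + 1L, nbins = 3L))
    data.frame(snp = sub("^g_", "", col),
               chisq = unname(ht$statistic), p = ht$p.value,
               allele_freq = unname(ht$estimate), n = length(g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' End-to-end reproduction of the analysis on an ingested or synthetic
#' cohort: phenotype preparation (month standardization, deficiency,
#' quintiles), Hardy-Weinberg QC, allele scores, the observational
#' association tables (phenotype-outcome, genotype-phenotype,
#' genotype-outcome), the instrument-confounder balance table, and the
#' instrument-by-adjustment grid of IV estimates. Outputs are written as TSV
#' plus a JSON manifest recording seeds and per-analysis sample sizes.
#'
#' @param input Path to a cohort CSV/TSV, or `NULL` to simulate.
#' @param config [sim_config()] used when `input` is `NULL`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Seed for simulation and bootstrap.
#' @param estimators Estimators for the IV grid.
#' @param boot Bootstrap resamples for the IV grid.
#' @param snps SNP specs for ingestion orientation.
#' @return Invisibly, a list with the prepared `cohort` and all result
#'   tables (`table1`, `table2`, `table3`, `table4`, `hwe`, `balance`,
#'   `manifest`).
#' @export
run_pipeline <- function(input = NULL, config = sim_config(),
                         out_dir = NULL, seed = 1L,
                         estimators = "control_function", boot = 500,
                         snps = default_snp_specs()) {
  if (is.null(input)) {
    cohort <- generate_cohort(config, seed = seed)
  } else {
    cohort <- ingest_cohort(input, snps = snps)
  }
  cohort <- prepare_phenotype(cohort)
  cohort <- add_allele_scores(cohort)

  covariate_sets <- list(crude = NULL, modelI = c("age", "sex"))
  model2 <- intersect(c("age", "sex", "deprivation", "energy", "smoking",
                        "bmi", "nsaid", "family_history", "activity"),
                      names(cohort))
  if (length(model2) > 2) covariate_sets$modelII <- model2

  hwe <- .hwe_table(cohort)
  table1 <- .table1(cohort, covariate_sets)
  table2 <- .genotype_table(cohort, "deficient")
  table3 <- .genotype_table(cohort, "y")
  balance <- balance_table(cohort)
  table4 <- run_mr_grid(cohort, methods = estimators, boot = boot,
                        seed = seed)

  manifest <- list(
    seed = seed,
    input = if (is.null(input)) "synthetic" else input,
    n = nrow(cohort),
    n_cases = sum(cohort$y == 1, na.rm = TRUE),
    n_controls = sum(cohort$y == 0, na.rm = TRUE),
    n_phenotyped = sum(!is.na(cohort$x_std)),
    estimators = estimators,
    bootstrap_resamples = boot,
    package_version = as.character(utils::packageVersion("vitdmr")),
    analyses = list(
      table1_n = unique(table1$n), table2_n = unique(table2$n),
      table3_n = unique(table3$n), table4_n = unique(stats::na.omit(table4$n)))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(obj, name)
      utils::write.table(obj, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    wt(hwe, "hwe"); wt(table1, "table1"); wt(table2, "table2")
    wt(table3, "table3"); wt(as.data.frame(table4), "table4")
    wt(balance, "balance")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    md <- c("# Mendelian randomization report",
            sprintf("- n = %d (%d cases / %d controls), seed %d",
                    manifest$n, manifest$n_cases, manifest$n_controls, seed),
            "", "## IV estimates (causal OR per ng/ml 25-OHD)", "",
            paste(utils::capture.output(print(table4)), collapse = "\n"))
    writeLines(md, file.path(out_dir, "report.md"))
  }

  invisible(list(cohort = cohort, hwe = hwe, table1 = table1,
                 table2 = table2, table3 = table3, table4 = table4,
                 balance = balance, manifest = manifest))
}
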