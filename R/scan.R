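#' Per-SNP association scan
#'
#' End-to-end pipeline: derive survival phenotypes, optionally exclude
#' prevalent cases, align and QC the genotype matrix, then for every
#' passing SNP run the score test of overall association and (optionally)
#' the maximum-likelihood overall and subtype-specific fits with the
#' heterogeneity test.  Genomic-control inflation (lambda and lambda1000)
#' and QQ coordinates are computed from the score-test p-values.  The scan
#' is deterministic given its inputs; errors for individual SNPs are
#' caught, recorded, and do not stop the scan.
#'
#' @param phenotypes Carrier phenotype table ([read_phenotypes()]).
#' @param genotypes A [genotype_matrix()].
#' @param incidence Carrier incidence curve(s); default per-gene curve.
#' @param classification Optional subtype classification column for the
#'   competing-risk fits (e.g. `"ER"`).
#' @param thresholds QC thresholds ([qc_thresholds()]).
#' @param exclude_prevalent_gap If non-`NULL`, drop affected carriers
#'   diagnosed at least this many years before recruitment.
#' @param fit `TRUE` to compute MLE hazard ratios per SNP (and subtype
#'   fits when `classification` is given); `FALSE` runs score tests only.
#' @param q Allele-frequency handling for the fits (see [carrier_fit()];
#'   default `"plugin"` for speed across many SNPs).
#' @param significance Named significance tiers recorded in the results:
#'   known susceptibility loci 0.05, reporting tier 1e-6, array-wide
#'   5e-8.
#' @param ages Analysis age grid.
#' @return Object of class `carrier_scan`: list with `results` (one row
#'   per QC-passing SNP), `qc` (per-variant QC report), `inflation`
#'   (lambda, lambda1000), `qq`, `counts` (filter bookkeeping:
#'   `n_input = n_pass + sum(n_fail)`), `errors`.
#' @export
carrier_scan <- function(phenotypes, genotypes, incidence = NULL,
                         classification = NULL,
                         thresholds = qc_thresholds(),
                         exclude_prevalent_gap = NULL, fit = TRUE,
                         q = "plugin",
                         significance = c(known_loci = 0.05,
                                          reporting = 1e-6,
                                          array_wide = 5e-8),
                         ages = 18:80) {
  sv <- derive_survival(phenotypes, classification = classification,
                        age_max = max(ages))
  if (!is.null(exclude_prevalent_gap))
    sv <- exclude_prevalent(sv, exclude_prevalent_gap)
  gm <- align_genotypes(genotypes, sv$carrier_id)
  qc <- variant_qc(gm, thresholds = thresholds, association = TRUE)
  kept <- qc$matrix
  incidence <- .resolve_incidence(incidence, sv, ages)

  n_cases <- sum(sv$d)
  n_controls <- sum(sv$d == 0L)
  sv1 <- sv; sv1$s <- NULL     # single-outcome records for the score test

  rows <- vector("list", nrow(kept$dosages))
  errors <- list()
  for (i in seq_len(nrow(kept$dosages))) {
    snp <- kept$variants$snp_id[i]
    dose <- kept$dosages[i, ]
    row <- data.frame(snp_id = snp, locus = kept$variants$chrom[i],
                      pos = kept$variants$pos[i],
                      ref = kept$variants$ref[i],
                      eff = kept$variants$eff[i],
                      maf = maf(kept)[i],
                      n = sum(!is.na(dose)),
                      n_events = sum(sv$d[!is.na(dose)]),
                      hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p_score = NA_real_, stringsAsFactors = FALSE)
    res <- tryCatch({
      st <- score_test(sv1, dose, incidence, ages = ages)
      row$p_score <- st$p_value
      if (fit) {
        fo <- carrier_fit(sv1, dose, incidence, q = q, ages = ages)
        ci <- confint(fo)
        row$hr <- fo$hr[[1L]]
        row$ci_low <- ci[1L, 1L]; row$ci_high <- ci[1L, 2L]
        if (!is.null(classification)) {
          fs <- carrier_fit(sv, dose, incidence, q = q, ages = ages)
          cis <- confint(fs)
          for (s in seq_along(fs$subtypes)) {
            pre <- fs$subtypes[s]
            row[[paste0("hr_", pre)]] <- fs$hr[[s]]
            row[[paste0("ci_low_", pre)]] <- cis[s, 1L]
            row[[paste0("ci_high_", pre)]] <- cis[s, 2L]
            row[[paste0("p_", pre)]] <-
              2 * stats::pnorm(-abs(fs$beta[[s]] / fs$se_robust[[s]]))
          }
          row$p_het <- if (!is.null(fs$heterogeneity))
            fs$heterogeneity$p_value else NA_real_
        }
      }
      row
    }, error = function(e) {
      errors[[snp]] <<- conditionMessage(e)
      row
    })
    rows[[i]] <- res
  }
  results <- do.call(rbind, rows)
  if (!is.null(results) && nrow(results)) {
    for (nm in names(significance))
      results[[paste0("sig_", nm)]] <- !is.na(results$p_score) &
        results$p_score < significance[[nm]]
  }
  pvals <- results$p_score[!is.na(results$p_score)]
  inflation <- if (length(pvals))
    genomic_inflation(pvals, n_cases, n_controls) else NULL
  qq <- if (length(pvals)) qq_points(pvals) else NULL
  fail_tab <- table(qc$report$fail_reason)
  counts <- list(n_carriers = nrow(sv), n_cases = n_cases,
                 n_controls = n_controls,
                 n_input = nrow(genotypes$dosages),
                 n_pass = sum(qc$report$pass),
                 n_fail = as.list(fail_tab))
  structure(list(results = results, qc = qc$report, inflation = inflation,
                 qq = qq, counts = counts, errors = errors,
                 significance = significance),
            class = "carrier_scan")
}

#' @export
print.carrier_scan <- function(x, ...) {
  cat("carrier_scan:", x$counts$n_input, "variants;",
      x$counts$n_pass, "passed QC;",
      x$counts$n_carriers, "carriers (",
      x$counts$n_cases, "affected )\n")
  if (!is.null(x$inflation))
    cat(sprintf("  lambda = %.3f, lambda1000 = %.3f\n",
                x$inflation$lambda, x$inflation$lambda1000))
  hits <- x$results$sig_known_loci
  if (!is.null(hits) && any(hits, na.rm = TRUE))
    cat("  SNPs below 0.05:",
        paste(x$results$snp_id[which(hits)], collapse = ", "), "\n")
  if (length(x$errors))
    cat("  errors:", length(x$errors), "SNP(s)\n")
  invisible(x)
}

#' Write scan results as TSV
#'
#' @param x A `carrier_scan`.
#' @param path Output file.
#' @export
write_scan_tsv <- function(x, path) {
  utils::write.table(x$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
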