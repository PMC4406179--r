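#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the p-value
#' sums the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param n0,n1,n2 Genotype counts (reference homozygote, heterozygote,
#'   effect homozygote).
#' @return The exact p-value.
#' @examples
#' hwe_exact_test(25, 50, 25)   # perfect HWE: p = 1
#' hwe_exact_test(50, 0, 50)    # gross deficit of heterozygotes
#' @export
hwe_exact_test <- function(n0, n1, n2) {
  if (any(c(n0, n1, n2) < 0) || any(c(n0, n1, n2) != round(c(n0, n1, n2))))
    stop("genotype counts must be non-negative integers")
  n <- n0 + n1 + n2
  if (n == 0) stop("total genotype count is zero")
  nA <- n1 + 2 * min(n0, n2)          # minor allele count (label-symmetric)
  # support of heterozygote counts with fixed allele counts
  het <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - het) / 2 + 1) - lgamma(het + 1) -
    lgamma(n - (nA + het) / 2 + 1) + het * log(2) +
    lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  p_obs <- logp[match(n1, het)]
  if (is.na(p_obs)) stop("inconsistent genotype counts")
  sum(exp(logp[logp <= p_obs + 1e-12]))
}

#' Default variant QC thresholds
#'
#' Call rate at least 0.95, exact HWE p at least 1e-7, non-monomorphic;
#' for association analyses additionally minor allele frequency at least
#' 0.03.
#'
#' @param call_rate,hwe_p,maf Threshold overrides.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(call_rate = 0.95, hwe_p = 1e-7, maf = 0.03) {
  list(call_rate = call_rate, hwe_p = hwe_p, maf = maf)
}

#' Variant quality control
#'
#' Applies the variant filters in a fixed order (call rate, monomorphic,
#' HWE, then - for association only - MAF) and records the first failing
#' rule per variant.  Deterministic and idempotent.
#'
#' @param x A [genotype_matrix()].
#' @param thresholds From [qc_thresholds()].
#' @param association Apply the MAF filter (default `TRUE`); with
#'   `FALSE` only basic genotyping QC is applied.
#' @return List with `report` (per-variant data frame: `snp_id`,
#'   `call_rate`, `maf`, `monomorphic`, `hwe_p`, `pass`, `fail_reason`)
#'   and `matrix` (the filtered [genotype_matrix()]).
#' @export
variant_qc <- function(x, thresholds = qc_thresholds(), association = TRUE) {
  cr <- call_rate(x)
  mf <- maf(x)
  mono <- apply(x$dosages, 1L, function(g) length(unique(g[!is.na(g)])) <= 1L)
  hwe <- apply(x$dosages, 1L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  fail <- rep(NA_character_, nrow(x$dosages))
  fail[is.na(fail) & cr < thresholds$call_rate] <- "call_rate"
  fail[is.na(fail) & mono] <- "monomorphic"
  fail[is.na(fail) & !is.na(hwe) & hwe < thresholds$hwe_p] <- "hwe"
  if (association)
    fail[is.na(fail) & mf < thresholds$maf] <- "maf"
  report <- data.frame(snp_id = x$variants$snp_id, call_rate = cr,
                       maf = mf, monomorphic = mono, hwe_p = hwe,
                       pass = is.na(fail), fail_reason = fail,
                       stringsAsFactors = FALSE)
  keep <- which(report$pass)
  list(report = report,
       matrix = genotype_matrix(x$dosages[keep, , drop = FALSE],
                                x$variants[keep, , drop = FALSE]))
}

# median of the chi-square(1) distribution; kept literal with a
# cross-check in the test suite against qchisq(0.5, 1)
.CHISQ1_MEDIAN <- 0.4549364

#' Genomic-control inflation
#'
#' `lambda` is the median association chi-square divided by the
#' chi-square(1) median (0.4549); `lambda1000` rescales the inflation to
#' an equivalent study of 1,000 cases and 1,000 controls:
#' `1 + (lambda - 1) (1/n_cases + 1/n_controls) / (2/1000)`.
#'
#' @param p Vector of association p-values in (0, 1].
#' @param n_cases,n_controls Effective case/control counts of the scan.
#' @return List with `lambda` and `lambda1000`.
#' @export
genomic_inflation <- function(p, n_cases, n_controls) {
  if (!length(p)) stop("empty p-value set")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (n_cases <= 0 || n_controls <= 0) stop("case/control counts must be positive")
  chisq <- stats::qchisq(p, 1L, lower.tail = FALSE)
  lambda <- stats::median(chisq) / .CHISQ1_MEDIAN
  lambda1000 <- 1 + (lambda - 1) * (1 / n_cases + 1 / n_controls) / (2 / 1000)
  list(lambda = lambda, lambda1000 = lambda1000)
}

#' Quantile-quantile coordinates for association p-values
#'
#' Expected quantiles use the rank formula `-log10(rank / (n + 1))`.
#' Variants can be excluded beforehand (e.g. SNPs placed on the array
#' because of previously reported associations).
#'
#' @param p Named or plain vector of p-values.
#' @param exclude Optional names/indices to drop before ranking.
#' @return Data frame with sorted `expected` and `observed` -log10 p.
#' @export
qq_points <- function(p, exclude = NULL) {
  if (!is.null(exclude)) {
    p <- if (is.character(exclude)) p[setdiff(names(p), exclude)]
    else p[-exclude]
  }
  p <- sort(as.numeric(p))
  n <- length(p)
  if (!n) stop("no p-values left")
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(p))[n:1, , drop = FALSE]
}
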