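#' Hazard ratio and confidence interval to the log scale
#'
#' Natural-log effect and its standard error recovered from a reported
#' 95\% interval: `se = (ln hi - ln lo) / (2 * 1.959964)`.  Intervals with
#' zero width are flagged degenerate.
#'
#' @param hr,ci_low,ci_high Hazard (or odds) ratio and its 95\% bounds.
#' @return Data frame with `log_effect`, `se`, `degenerate`.
#' @examples
#' hr_to_logscale(1.24, 1.18, 1.31)
#' @export
hr_to_logscale <- function(hr, ci_low, ci_high) {
  bad <- which(!(ci_low > 0 & ci_low <= hr & hr <= ci_high))
  bad <- bad[!is.na(bad) & !is.na(hr[bad] + ci_low[bad] + ci_high[bad])]
  if (length(bad))
    stop("CI ordering violated (need 0 < ci_low <= hr <= ci_high) at row ",
         bad[1])
  se <- (log(ci_high) - log(ci_low)) / (2 * 1.959964)
  data.frame(log_effect = log(hr), se = se,
             degenerate = !is.na(se) & se == 0)
}

#' One-way random-effects intraclass correlation
#'
#' Shrout-Fleiss single-measurement ICC under the one-way random-effects
#' model, used to quantify absolute agreement between two sets of
#' per-variant log hazard ratios (each SNP is a "target" rated by the two
#' analyses).  With `n` complete pairs and `k = 2`,
#' `ICC = (MSB - MSW) / (MSB + (k-1) MSW)`; the 95\% confidence interval
#' is based on `F = MSB/MSW` with `(n - 1, n)` degrees of freedom.
#' Pairs with a missing value in either vector are dropped.
#'
#' @param x,y Numeric vectors of paired measurements (e.g. log HRs for the
#'   same SNPs from two cohorts).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `icc_oneway`: list with `icc`, `ci_low`,
#'   `ci_high`, `n_pairs`, `n_dropped`, `msb`, `msw`.
#' @examples
#' icc_oneway(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' @export
icc_oneway <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x); k <- 2
  if (n < 3L) stop("at least 3 complete pairs are required")
  m <- cbind(x, y)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both vectors are constant; ICC undefined")
  rowm <- rowMeans(m)
  msb <- k * sum((rowm - mean(m))^2) / (n - 1)
  msw <- sum((m - rowm)^2) / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - conf
  F_obs <- msb / msw
  F_u <- stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
  F_l <- stats::qf(alpha / 2, n - 1, n * (k - 1))
  ci <- c((F_obs / F_u - 1) / (F_obs / F_u + k - 1),
          (F_obs / F_l - 1) / (F_obs / F_l + k - 1))
  structure(list(icc = icc, ci_low = min(ci), ci_high = max(ci),
                 n_pairs = n, n_dropped = dropped, msb = msb, msw = msw,
                 conf = conf),
            class = "icc_oneway")
}

#' @export
print.icc_oneway <- function(x, digits = 2, ...) {
  cat(sprintf("one-way random-effects ICC = %.*f (%g%% CI: %.*f to %.*f), n = %d pairs",
              digits, x$icc, 100 * x$conf, digits, x$ci_low, digits,
              x$ci_high, x$n_pairs))
  if (x$n_dropped) cat(sprintf(" (%d incomplete pairs dropped)", x$n_dropped))
  cat("\n")
  invisible(x)
}

#' Read a long-format effect table
#'
#' Tab-separated table with columns `snp_id`, `arm`, `hr`, `ci_low`,
#' `ci_high`; each arm is one analysis (cohort x endpoint).
#'
#' @param path TSV file path.
#' @return Data frame with the five columns plus `log_effect`, `se`.
#' @export
read_effect_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "arm", "hr", "ci_low", "ci_high")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("effect table missing column(s): ",
                         paste(miss, collapse = ", "))
  cbind(d, hr_to_logscale(d$hr, d$ci_low, d$ci_high)[c("log_effect", "se")])
}

#' Pairwise ICC grid across analysis arms
#'
#' Computes the one-way random-effects ICC on signed natural-log effects
#' for every pair of arms, matching variants by `snp_id` and dropping
#' incomplete pairs per cell.  `magnitude = TRUE` compares absolute log
#' effects instead (an alternative reading of "agreement in absolute
#' values").
#'
#' @param effects Long effect table as from [read_effect_table()] or
#'   [susceptibility_loci()].
#' @param arms Arms to compare (default: all arms present).
#' @param magnitude Compare `|log HR|` instead of signed log HR.
#' @return Matrix of ICC estimates (arms x arms, unit diagonal), with the
#'   full per-cell [icc_oneway()] objects in attribute `details` and pair
#'   counts in attribute `n_pairs`.
#' @export
icc_grid <- function(effects, arms = NULL, magnitude = FALSE) {
  if (is.null(arms)) arms <- unique(effects$arm)
  if (length(arms) < 2L) stop("at least two arms are required")
  val <- if (magnitude) abs(effects$log_effect) else effects$log_effect
  by_arm <- lapply(arms, function(a) {
    rows <- effects$arm == a
    stats::setNames(val[rows], effects$snp_id[rows])
  })
  names(by_arm) <- arms
  snps <- unique(effects$snp_id)
  k <- length(arms)
  out <- matrix(NA_real_, k, k, dimnames = list(arms, arms))
  npair <- matrix(NA_integer_, k, k, dimnames = list(arms, arms))
  details <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { out[i, j] <- 1; next }
    cell <- tryCatch(icc_oneway(by_arm[[i]][snps], by_arm[[j]][snps]),
                     error = function(e) e)
    if (inherits(cell, "error")) {
      details[[paste(arms[i], arms[j], sep = " vs ")]] <- conditionMessage(cell)
    } else {
      out[i, j] <- cell$icc
      npair[i, j] <- cell$n_pairs
      details[[paste(arms[i], arms[j], sep = " vs ")]] <- cell
    }
  }
  structure(out, n_pairs = npair, details = details)
}

#' Published hazard ratios for the 74 breast-cancer susceptibility loci
#'
#' Per-SNP hazard ratio estimates (with 95\% CIs and p-values) for overall,
#' ER-negative and ER-positive breast cancer in BRCA1 and BRCA2 mutation
#' carriers, for the 74 breast-cancer susceptibility variants reported by
#' population-based studies up to April 2013.  The values are a
#' transcription of the consortium-published association table shipped
#' with the package for cross-cohort agreement analyses; cells the source
#' left blank (one low-frequency variant's subtype columns) are `NA`.
#'
#' @param long Return the long effect-table format (default); with
#'   `FALSE` the raw wide transcription.
#' @return Long format: data frame with `snp_id`, `locus`, `arm` (one of
#'   `BRCA1.overall`, `BRCA1.erneg`, `BRCA1.erpos`, `BRCA2.overall`,
#'   `BRCA2.erneg`, `BRCA2.erpos`), `hr`, `ci_low`, `ci_high`, `p`,
#'   `log_effect`, `se`.
#' @export
susceptibility_loci <- function(long = TRUE) {
  path <- system.file("extdata", "susceptibility_loci_hr.csv",
                      package = "carriermod", mustWork = TRUE)
  wide <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!long) return(wide)
  arms <- c(BRCA1.overall = "b1_overall", BRCA1.erneg = "b1_erneg",
            BRCA1.erpos = "b1_erpos", BRCA2.overall = "b2_overall",
            BRCA2.erneg = "b2_erneg", BRCA2.erpos = "b2_erpos")
  out <- do.call(rbind, lapply(names(arms), function(a) {
    pre <- arms[[a]]
    data.frame(snp_id = wide$snp_id, locus = wide$locus, arm = a,
               hr = wide[[paste0(pre, "_hr")]],
               ci_low = wide[[paste0(pre, "_lo")]],
               ci_high = wide[[paste0(pre, "_hi")]],
               p = wide[[paste0(pre, "_p")]],
               stringsAsFactors = FALSE)
  }))
  ok <- !is.na(out$hr)
  logs <- hr_to_logscale(out$hr[ok], out$ci_low[ok], out$ci_high[ok])
  out$log_effect <- NA_real_; out$se <- NA_real_
  out$log_effect[ok] <- logs$log_effect
  out$se[ok] <- logs$se
  rownames(out) <- NULL
  out
}

#' Cross-cohort comparison of effect tables
#'
#' Convenience wrapper building the pairwise ICC agreement grid for one or
#' more effect tables (stacked long format), mirroring a
#' cohort-by-endpoint comparison table.
#'
#' @param tables Named list of long effect tables, or a single table.
#' @param arms Optional arm subset/order.
#' @param magnitude Compare absolute log effects.
#' @return See [icc_grid()].
#' @export
compare_effect_tables <- function(tables, arms = NULL, magnitude = FALSE) {
  if (is.data.frame(tables)) tables <- list(tables)
  stacked <- do.call(rbind, lapply(seq_along(tables), function(i) {
    d <- tables[[i]]
    nm <- names(tables)[i]
    if (!is.null(nm) && nzchar(nm) && length(tables) > 1L)
      d$arm <- paste(nm, d$arm, sep = ".")
    d
  }))
  icc_grid(stacked, arms = arms, magnitude = magnitude)
}
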