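#' Age-specific carrier breast-cancer incidence curves
#'
#' The retrospective likelihood pins the baseline hazard to an external
#' age-specific breast-cancer incidence curve for mutation carriers
#' ("penetrance curve").  These curves are an input to the analysis, not
#' something the model estimates.  `default_incidence()` returns a smooth
#' illustrative curve per gene with the magnitude and shape of published
#' carrier penetrance estimates (steep rise through the forties for BRCA1,
#' a later and slightly lower rise for BRCA2).  They are synthetic defaults
#' intended for simulation and testing; real analyses should supply
#' cohort-appropriate curves via [read_incidence()].
#'
#' @param gene `"BRCA1"` or `"BRCA2"`.
#' @param ages Integer age grid (whole years).
#' @return A data frame with columns `gene`, `age`, `rate`; rates are
#'   incidences per person-year, strictly inside (0, 1).
#' @examples
#' mu <- default_incidence("BRCA1")
#' plot(mu$age, mu$rate, type = "l", xlab = "age", ylab = "incidence")
#' @export
default_incidence <- function(gene = c("BRCA1", "BRCA2"), ages = 18:80) {
  gene <- match.arg(gene)
  # knot values (incidence per person-year) at decade anchors
  knots <- list(
    BRCA1 = cbind(age = c(18, 25, 30, 35, 40, 45, 50, 60, 70, 80),
                  rate = c(5e-4, 4e-3, 1.1e-2, 2.2e-2, 2.9e-2, 3.0e-2,
                           2.8e-2, 2.5e-2, 2.4e-2, 2.3e-2)),
    BRCA2 = cbind(age = c(18, 25, 30, 35, 40, 45, 50, 60, 70, 80),
                  rate = c(3e-4, 2e-3, 6e-3, 1.2e-2, 1.8e-2, 2.2e-2,
                           2.4e-2, 2.2e-2, 2.1e-2, 2.0e-2))
  )[[gene]]
  rate <- stats::approx(knots[, "age"], knots[, "rate"], xout = ages,
                        rule = 2)$y
  data.frame(gene = gene, age = as.integer(ages), rate = rate)
}

#' Read an incidence curve from CSV
#'
#' Expects columns `gene`, `age`, `rate` (incidence per person-year).
#'
#' @param path CSV file path.
#' @param gene Optional gene to filter on when the file holds several curves.
#' @return Data frame with columns `gene`, `age`, `rate`.
#' @export
read_incidence <- function(path, gene = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "age", "rate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("incidence file is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(gene)) d <- d[d$gene == gene, , drop = FALSE]
  if (!nrow(d)) stop("no incidence rows", if (!is.null(gene)) paste0(" for gene ", gene))
  if (any(!is.finite(d$rate)) || any(d$rate <= 0) || any(d$rate >= 1))
    stop("incidence rates must lie strictly in (0, 1)")
  d[order(d$age), c("gene", "age", "rate")]
}

# Extract the rate vector for an integer age grid, erroring on gaps.
.incidence_on_grid <- function(incidence, ages) {
  if (is.numeric(incidence) && is.null(dim(incidence))) {
    if (length(incidence) != length(ages))
      stop("incidence vector length does not match the age grid")
    mu <- as.numeric(incidence)
  } else {
    idx <- match(ages, incidence$age)
    if (anyNA(idx))
      stop("incidence curve does not cover age(s) ",
           paste(ages[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
    mu <- incidence$rate[idx]
  }
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1))
    stop("incidence rates must lie strictly in (0, 1)")
  mu
}
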