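#' Read a carrier phenotype table
#'
#' One row per genotyped mutation carrier.  Required columns:
#' `carrier_id`, `family_id`, `gene`, `stratum`, `age_bc`, `age_oc`,
#' `age_mastectomy`, `age_last_followup`, `age_recruitment`.  Any further
#' columns are kept as tumor-subtype classifications (e.g. `ER`, `PR`,
#' `HER2`) whose values are category labels; empty cells are missing.
#' Eligibility requires carriers aged 18 or older at last follow-up, and
#' event ages are bounded by `age_max`.
#'
#' @param path Tab-separated phenotype file with a header row.
#' @param age_max Upper bound of the analysis age grid (default 80); ages
#'   above it are permitted in the file and are censored downstream.
#' @return A data frame of carrier records; age columns numeric with `NA`
#'   for missing, label columns character with `NA` for missing.
#' @seealso [derive_survival()] for the censoring rules applied downstream.
#' @export
read_phenotypes <- function(path, age_max = 80) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  required <- c("carrier_id", "family_id", "gene", "stratum", "age_bc",
                "age_oc", "age_mastectomy", "age_last_followup",
                "age_recruitment")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("phenotype file is missing required column(s): ",
         paste(miss, collapse = ", "))
  age_cols <- grep("^age_", required, value = TRUE)
  for (col in age_cols) {
    raw <- d[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           ": '", raw[bad[1]], "'")
    d[[col]] <- num
  }
  dup <- d$carrier_id[duplicated(d$carrier_id)]
  if (length(dup))
    stop("duplicate carrier_id: ", paste(unique(dup)[1:min(3, length(unique(dup)))],
                                         collapse = ", "))
  if (anyNA(d$age_last_followup))
    stop("age_last_followup is required for every carrier (missing at row ",
         which(is.na(d$age_last_followup))[1], ")")
  under <- which(d$age_last_followup < 18)
  if (length(under))
    stop("carrier '", d$carrier_id[under[1]],
         "' has age_last_followup < 18; eligibility requires age 18 or older")
  for (col in age_cols) {
    lo <- which(!is.na(d[[col]]) & d[[col]] < 18)
    if (length(lo))
      stop("carrier '", d$carrier_id[lo[1]], "' has ", col, " < 18")
  }
  bad_gene <- setdiff(unique(d$gene), c("BRCA1", "BRCA2"))
  if (length(bad_gene))
    stop("gene must be BRCA1 or BRCA2; found: ",
         paste(bad_gene, collapse = ", "))
  d
}

#' Derive analysis-ready survival records from carrier phenotypes
#'
#' Applies the carrier censoring rule: each woman is censored at the first
#' of breast cancer diagnosis, ovarian cancer diagnosis, bilateral
#' prophylactic mastectomy, or last follow-up.  Ages are discretized to
#' whole years (floor); when breast cancer ties with another censoring
#' event at the same integer age the breast cancer event is counted.
#' Events past `age_max` are censored at `age_max`.
#'
#' @param phenotypes Data frame from [read_phenotypes()].
#' @param classification Optional name of a subtype classification column;
#'   its label is carried into `s` for affected carriers (`NA` for
#'   unaffected carriers or missing pathology).
#' @param age_max Upper bound of the analysis age grid (default 80).
#' @return A data frame with one row per carrier: `carrier_id`,
#'   `family_id`, `stratum`, `gene`, `t` (integer age at event/censoring),
#'   `d` (0/1 breast-cancer indicator), `s` (factor subtype label or `NA`),
#'   and `prevalent_gap` (years from diagnosis to recruitment, affected
#'   carriers with both ages only).
#' @examples
#' ph <- data.frame(carrier_id = "a", family_id = "f", gene = "BRCA1",
#'                  stratum = "UK", age_bc = 45, age_oc = 43,
#'                  age_mastectomy = NA, age_last_followup = 50,
#'                  age_recruitment = 44)
#' derive_survival(ph)  # censored at the ovarian diagnosis: t = 43, d = 0
#' @export
derive_survival <- function(phenotypes, classification = NULL, age_max = 80) {
  p <- phenotypes
  ev <- cbind(bc = floor(p$age_bc), oc = floor(p$age_oc),
              mast = floor(p$age_mastectomy), fu = floor(p$age_last_followup))
  all_missing <- apply(ev, 1L, function(r) all(is.na(r)))
  if (any(all_missing))
    stop("carrier '", p$carrier_id[which(all_missing)[1]],
         "' has no event or follow-up age; cannot censor")
  t <- apply(ev, 1L, min, na.rm = TRUE)
  d <- as.integer(!is.na(ev[, "bc"]) & ev[, "bc"] == t)
  # events or censoring beyond the grid are censored at age_max
  over <- t > age_max
  t[over] <- age_max
  d[over] <- 0L
  s <- rep(NA_character_, nrow(p))
  if (!is.null(classification)) {
    if (!classification %in% names(p))
      stop("classification column '", classification, "' not found")
    s[d == 1L] <- as.character(p[[classification]])[d == 1L]
  }
  gap <- rep(NA_real_, nrow(p))
  both <- d == 1L & !is.na(p$age_recruitment) & !is.na(p$age_bc)
  gap[both] <- p$age_recruitment[both] - p$age_bc[both]
  out <- data.frame(carrier_id = p$carrier_id, family_id = p$family_id,
                    stratum = p$stratum, gene = p$gene,
                    t = as.integer(t), d = d,
                    s = factor(s), prevalent_gap = gap,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exclude prevalent breast-cancer cases
#'
#' Sensitivity filter against survival bias: removes affected carriers
#' diagnosed `gap_years` or more years before study recruitment.
#' Unaffected carriers, and affected carriers lacking a recruitment age,
#' are always retained (the number retained for lack of a recruitment age
#' is recorded in the `n_unknown_gap` attribute).
#'
#' @param survival Data frame from [derive_survival()].
#' @param gap_years Minimum diagnosis-to-recruitment gap for removal
#'   (default 5; must be positive).
#' @return The filtered data frame, with attributes `n_removed` and
#'   `n_unknown_gap`.
#' @export
exclude_prevalent <- function(survival, gap_years = 5) {
  if (!is.numeric(gap_years) || gap_years <= 0)
    stop("gap_years must be positive")
  drop <- survival$d == 1L & !is.na(survival$prevalent_gap) &
    survival$prevalent_gap >= gap_years
  unknown <- survival$d == 1L & is.na(survival$prevalent_gap)
  out <- survival[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  attr(out, "n_unknown_gap") <- sum(unknown)
  out
}

#' Triple-negative status from receptor columns
#'
#' Builds a TN / non-TN classification from `ER`, `PR` and `HER2` columns.
#' Only tumors with complete information on all three receptors are
#' classified; any incomplete record gets `NA` and enters subtype analyses
#' as a missing label.
#'
#' @param phenotypes Phenotype data frame with `ER`, `PR`, `HER2` columns
#'   coded `"positive"`/`"negative"`.
#' @return Character vector, `"TN"`, `"non-TN"` or `NA`.
#' @export
derive_tn <- function(phenotypes) {
  er <- phenotypes$ER; pr <- phenotypes$PR; her2 <- phenotypes$HER2
  if (is.null(er) || is.null(pr) || is.null(her2))
    stop("ER, PR and HER2 columns are all required for TN classification")
  complete <- !is.na(er) & !is.na(pr) & !is.na(her2)
  out <- rep(NA_character_, nrow(phenotypes))
  tn <- complete & er == "negative" & pr == "negative" & her2 == "negative"
  out[complete] <- ifelse(tn[complete], "TN", "non-TN")
  out
}

#' Pool small strata
#'
#' Country-level strata with fewer than `min_n` usable carriers are merged:
#' either via an explicit `map` (named character vector, stratum ->
#' group, mirroring the pooling of geographically close countries) or, for
#' unmapped small strata, into a single `"pooled"` group.
#'
#' @param stratum Character vector of stratum labels.
#' @param min_n Minimum carriers for a stratum to stand alone (default 50).
#' @param map Optional named character vector mapping strata to pooled
#'   groups.
#' @return Character vector of pooled stratum labels.
#' @export
pool_strata <- function(stratum, min_n = 50, map = NULL) {
  out <- as.character(stratum)
  if (!is.null(map)) {
    hit <- out %in% names(map)
    out[hit] <- unname(map[out[hit]])
  }
  tab <- table(out)
  small <- setdiff(names(tab)[tab < min_n], unname(map))  # mapped groups stand
  if (length(small) > 1L || (length(small) == 1L && length(tab) > 1L))
    out[out %in% small] <- "pooled"
  out
}
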