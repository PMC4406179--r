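#' Simulate a family-structured mutation-carrier cohort
#'
#' Generates synthetic carrier cohorts with the statistical structure the
#' retrospective-likelihood analysis assumes, so that every pipeline stage
#' can be validated without access to consortium data.  Families are
#' sibships of configurable size descending from two unobserved founders
#' whose genotypes are drawn under Hardy-Weinberg equilibrium at the
#' configured allele frequency; sibling genotypes are transmitted
#' Mendelianly, which induces the within-family genotype correlation that
#' the clustered sandwich variance is designed to absorb.  The yearly
#' disease process uses subtype-specific hazards
#' `lambda0_s(t) exp(beta_s z)` whose baselines solve the same calibration
#' constraints as the estimator (see [calibrate_baseline()]), so the
#' generator and the fitting engine share one model.  Competing censoring
#' events (ovarian cancer, bilateral mastectomy, end of follow-up) are
#' applied; under proband ascertainment, a designated proband (the first
#' family member) must be affected for the family to enter the cohort,
#' emulating recruitment through cancer genetics clinics.
#'
#' @param n_families Number of families retained in the cohort.
#' @param family_size Carriers per family (sibship size; 1 gives
#'   unrelated carriers).
#' @param gene `"BRCA1"` or `"BRCA2"` (selects the default incidence).
#' @param maf Effect-allele frequency of the causal SNP.
#' @param hr Per-allele hazard ratio(s): scalar for a single outcome, a
#'   vector for one HR per tumor subtype.
#' @param subtypes Subtype labels; defaults to
#'   `c("positive", "negative")` for two subtypes.
#' @param f Subtype mixture proportions (defaults to `c(0.25, 0.75)` for
#'   two subtypes - roughly the ER-positive share among labeled BRCA1
#'   tumors - and uniform otherwise).
#' @param incidence Carrier incidence curve (default
#'   [default_incidence()]).
#' @param ascertainment `"population"` (random carriers) or `"proband"`
#'   (families kept only when the proband is affected).
#' @param missing_label Probability that an affected carrier's subtype
#'   label is masked (default 0.4, matching the roughly 60\% pathology
#'   coverage of carrier cohorts; missing completely at random).
#' @param mnar_shift Additional masking probability applied to the last
#'   subtype only - a stress mode that violates the missing-at-random
#'   assumption (default 0).
#' @param missing_geno Probability that a dosage call fails (per carrier
#'   and SNP).
#' @param oc_rate Yearly ovarian-cancer censoring rate from age 40.
#' @param mastectomy_rate Yearly bilateral-mastectomy rate from age 25.
#' @param followup_mean,followup_sd Normal distribution of the end of
#'   follow-up age (rounded, clamped to the grid).
#' @param prevalent_max_gap Recruitment of affected carriers occurs 0 to
#'   this many years after diagnosis (uniform).
#' @param n_null_snps Extra null SNPs (independent of the phenotype)
#'   simulated with the same family structure.
#' @param null_maf Allele frequency of the null SNPs (recycled).
#' @param classification Name of the subtype column in the phenotype
#'   table (default `"subtype"`).
#' @param stratum Stratum label (recycled).
#' @param ages Analysis age grid.
#' @param seed Integer seed; mandatory, all output is a pure function of
#'   the configuration including the seed.
#' @return A list of class `carrier_sim`: `phenotypes` (carrier phenotype
#'   table in the layout of [read_phenotypes()]), `genotypes`
#'   (a [genotype_matrix()]; the causal SNP is named `"causal"`), and
#'   `truth` (configuration, per-carrier latent state and founder
#'   genotypes).
#' @export
simulate_carriers <- function(n_families = 500, family_size = 1,
                              gene = c("BRCA1", "BRCA2"), maf = 0.3,
                              hr = 1.0, subtypes = NULL, f = NULL,
                              incidence = NULL,
                              ascertainment = c("population", "proband"),
                              missing_label = if (length(hr) > 1) 0.4 else 0,
                              mnar_shift = 0, missing_geno = 0,
                              oc_rate = 0.004, mastectomy_rate = 0.002,
                              followup_mean = 55, followup_sd = 12,
                              prevalent_max_gap = 8,
                              n_null_snps = 0, null_maf = 0.3,
                              classification = "subtype",
                              stratum = "SIM", ages = 18:80, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  gene <- match.arg(gene)
  ascertainment <- match.arg(ascertainment)
  beta <- log(hr)
  S <- length(beta)
  if (is.null(subtypes))
    subtypes <- if (S == 2L) c("positive", "negative")
                else paste0("class", seq_len(S))
  if (is.null(f)) f <- if (S == 2L) c(0.25, 0.75) else rep(1 / S, S)
  if (length(f) != S || abs(sum(f) - 1) > 1e-8)
    stop("f must be a length-S probability vector")
  if (is.null(incidence)) incidence <- default_incidence(gene, ages)
  lam <- calibrate_baseline(beta, maf, incidence, ages = ages,
                            f = if (S > 1L) f else NULL)

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  # genotype hazards: 3 x nA total, and subtype shares
  z <- 0:2
  E <- exp(outer(beta, z))                  # S x 3
  H <- t(crossprod(lam, E))                 # 3 x nA total hazard
  nA <- length(ages)

  kept <- list(); n_kept <- 0L; fam_offset <- 0L; iter <- 0L
  while (n_kept < n_families) {
    iter <- iter + 1L
    if (iter > 60L) stop("infeasible configuration: ascertainment keeps rejecting families")
    batch <- if (ascertainment == "population") n_families - n_kept
             else max(64L, ceiling((n_families - n_kept) * 2.5))
    b <- .sim_family_batch(batch, family_size, maf, H, lam, E, S, ages,
                           oc_rate, mastectomy_rate, followup_mean,
                           followup_sd)
    keep_fam <- if (ascertainment == "proband") {
      aff <- b$affected & b$member == 1L
      sort(unique(b$fam[aff]))
    } else seq_len(batch)
    keep_fam <- keep_fam[seq_len(min(length(keep_fam), n_families - n_kept))]
    if (length(keep_fam)) {
      sel <- b$fam %in% keep_fam
      b <- lapply(b, function(v) if (is.matrix(v)) v[, keep_fam, drop = FALSE]
                  else v[sel])
      b$fam <- match(b$fam, keep_fam) + fam_offset
      kept[[length(kept) + 1L]] <- b
      n_kept <- n_kept + length(keep_fam)
      fam_offset <- fam_offset + length(keep_fam)
    }
  }
  fam <- unlist(lapply(kept, `[[`, "fam"))
  member <- unlist(lapply(kept, `[[`, "member"))
  g <- unlist(lapply(kept, `[[`, "g"))
  t_bc <- unlist(lapply(kept, `[[`, "t_bc"))
  t_oc <- unlist(lapply(kept, `[[`, "t_oc"))
  t_mast <- unlist(lapply(kept, `[[`, "t_mast"))
  t_fu <- unlist(lapply(kept, `[[`, "t_fu"))
  s_true <- unlist(lapply(kept, `[[`, "s_true"))
  founders <- do.call(cbind, lapply(kept, `[[`, "founders"))
  affected <- !is.na(t_bc)
  n <- length(fam)

  # recruitment: at censoring for unaffected; 0..gap years after diagnosis
  cens_age <- pmin(ifelse(is.na(t_bc), Inf, t_bc), ifelse(is.na(t_oc), Inf, t_oc),
                   ifelse(is.na(t_mast), Inf, t_mast), t_fu)
  recr <- cens_age
  gap <- sample.int(prevalent_max_gap + 1L, n, replace = TRUE) - 1L
  recr[affected] <- pmin(t_bc[affected] + gap[affected], max(ages))
  recr <- pmax(recr, 18)

  # subtype labels with (optionally MNAR) masking
  lab <- rep(NA_character_, n)
  if (S > 1L) {
    lab[affected] <- subtypes[s_true[affected]]
    pmask <- missing_label + mnar_shift * (s_true == S)
    mask <- affected & stats::runif(n) < pmask
    lab[mask] <- NA_character_
  }

  carrier_id <- sprintf("F%04d_I%d", fam, member)
  phen <- data.frame(carrier_id = carrier_id,
                     family_id = sprintf("F%04d", fam),
                     gene = gene, stratum = rep_len(stratum, n),
                     age_bc = t_bc, age_oc = t_oc, age_mastectomy = t_mast,
                     age_last_followup = pmax(t_fu, cens_age, na.rm = TRUE),
                     age_recruitment = recr,
                     stringsAsFactors = FALSE)
  phen$age_last_followup <- pmax(phen$age_last_followup, 18)
  if (S > 1L) phen[[classification]] <- lab

  # genotype matrix: causal SNP plus optional null SNPs
  snp_ids <- c("causal", if (n_null_snps > 0)
    sprintf("null_%04d", seq_len(n_null_snps)))
  dos <- matrix(NA_integer_, length(snp_ids), n,
                dimnames = list(snp_ids, carrier_id))
  dos[1L, ] <- g
  null_founders <- NULL
  if (n_null_snps > 0) {
    nm <- rep_len(null_maf, n_null_snps)
    ng <- simulate_family_genotypes(fam, nm, seed = seed + 1L)
    dos[-1L, ] <- ng$dosages
    null_founders <- ng$founders
  }
  if (missing_geno > 0)
    dos[matrix(stats::runif(length(dos)) < missing_geno, nrow(dos))] <- NA_integer_
  variants <- data.frame(snp_id = snp_ids, chrom = "1",
                         pos = seq_along(snp_ids) * 1000L,
                         ref = "A", eff = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, variants)

  truth <- list(config = list(n_families = n_families,
                              family_size = family_size, gene = gene,
                              maf = maf, hr = hr, beta = beta, f = f,
                              subtypes = subtypes,
                              ascertainment = ascertainment,
                              missing_label = missing_label,
                              mnar_shift = mnar_shift,
                              missing_geno = missing_geno,
                              oc_rate = oc_rate,
                              mastectomy_rate = mastectomy_rate,
                              followup_mean = followup_mean,
                              followup_sd = followup_sd, seed = seed),
                genotype = g, subtype = s_true, family = fam,
                founders = founders, null_founders = null_founders,
                baseline = lam)
  structure(list(phenotypes = phen, genotypes = gm, truth = truth),
            class = "carrier_sim")
}

#' @export
print.carrier_sim <- function(x, ...) {
  cat("carrier_sim:", nrow(x$phenotypes), "carriers in",
      length(unique(x$phenotypes$family_id)), "families;",
      sum(!is.na(x$phenotypes$age_bc)), "affected\n")
  invisible(x)
}

# One batch of families: genotypes and the yearly disease process.
.sim_family_batch <- function(n_fam, fam_size, q, H, lam, E, S, ages,
                              oc_rate, mast_rate, fu_mean, fu_sd) {
  n <- n_fam * fam_size
  fam <- rep(seq_len(n_fam), each = fam_size)
  member <- rep(seq_len(fam_size), times = n_fam)
  f1 <- stats::rbinom(n_fam, 2L, q)
  f2 <- stats::rbinom(n_fam, 2L, q)
  g <- stats::rbinom(n, 1L, f1[fam] / 2) + stats::rbinom(n, 1L, f2[fam] / 2)

  nA <- length(ages)
  fu <- pmin(pmax(round(stats::rnorm(n, fu_mean, fu_sd)), 19L), max(ages))
  t_bc <- t_oc <- t_mast <- rep(NA_real_, n)
  s_true <- rep(NA_integer_, n)
  active <- rep(TRUE, n)
  for (a in seq_len(nA)) {
    age <- ages[a]
    live <- which(active & fu >= age)   # the follow-up year itself is at risk
    if (!length(live)) break
    hg <- H[g[live] + 1L, a]
    ev <- stats::runif(length(live)) < -expm1(-hg)
    hit <- live[ev]
    if (length(hit)) {
      t_bc[hit] <- age
      if (S > 1L) {
        sh <- t(lam[, a] * E[, g[hit] + 1L, drop = FALSE])  # n_hit x S
        s_true[hit] <- apply(sh, 1L, function(w)
          sample.int(S, 1L, prob = w))
      } else s_true[hit] <- 1L
      active[hit] <- FALSE
      live <- setdiff(live, hit)
    }
    if (length(live) && age >= 40) {
      oc <- live[stats::runif(length(live)) < -expm1(-oc_rate)]
      t_oc[oc] <- age; active[oc] <- FALSE
      live <- setdiff(live, oc)
    }
    if (length(live) && age >= 25) {
      ms <- live[stats::runif(length(live)) < -expm1(-mast_rate)]
      t_mast[ms] <- age; active[ms] <- FALSE
    }
  }
  list(fam = fam, member = member, g = g, t_bc = t_bc, t_oc = t_oc,
       t_mast = t_mast, t_fu = fu, s_true = s_true,
       affected = !is.na(t_bc), founders = rbind(f1, f2))
}

#' Simulate null SNP genotypes on an existing family structure
#'
#' Draws founder genotypes under HWE and transmits alleles Mendelianly to
#' the carriers of each family; the SNPs are independent of any phenotype
#' (and of each other), suitable for null-calibration scans.
#'
#' @param family Integer/character family id per carrier.
#' @param maf Allele frequency per SNP (recycled to `n_snps` when scalar).
#' @param n_snps Number of SNPs (default `length(maf)`).
#' @param seed Integer seed.
#' @return List with `dosages` (SNPs x carriers) and `founders`
#'   (2`n_snps` x families array of founder dosages).
#' @export
simulate_family_genotypes <- function(family, maf, n_snps = length(maf),
                                      seed) {
  if (missing(seed)) stop("a seed is mandatory")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  maf <- rep_len(maf, n_snps)
  fam <- as.integer(factor(family))
  n_fam <- max(fam)
  n <- length(fam)
  dos <- matrix(NA_integer_, n_snps, n)
  founders <- array(NA_integer_, c(2L, n_fam, n_snps))
  for (j in seq_len(n_snps)) {
    f1 <- stats::rbinom(n_fam, 2L, maf[j])
    f2 <- stats::rbinom(n_fam, 2L, maf[j])
    dos[j, ] <- stats::rbinom(n, 1L, f1[fam] / 2) +
      stats::rbinom(n, 1L, f2[fam] / 2)
    founders[1L, , j] <- f1
    founders[2L, , j] <- f2
  }
  list(dosages = dos, founders = founders)
}

#' Write a deterministic suite of named test fixtures
#'
#' Emits small cohorts covering the scenarios the pipeline must handle:
#' `null_snp` (no association), `er_specific` (subtype-specific effect,
#' HR 1.3 vs 1.0), `family_clustered` (sibships of 4),
#' `high_missing` (70\% missing labels, 10\% failed calls) and
#' `qc_fail` (three planted QC-failing variants: call rate 0.94, gross
#' HWE violation, MAF 0.02).  Each fixture gets a phenotype TSV, a dosage
#' TSV and a flat key=value truth manifest; identical seeds give
#' byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a named list of the per-fixture file paths.
#' @export
make_fixture_suite <- function(dir, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  specs <- list(
    null_snp = list(n_families = 250, family_size = 2, hr = 1.0),
    er_specific = list(n_families = 250, family_size = 2,
                       hr = c(1.3, 1.0), classification = "ER"),
    family_clustered = list(n_families = 100, family_size = 4, hr = 1.2),
    high_missing = list(n_families = 250, family_size = 2,
                        hr = c(1.3, 1.0), classification = "ER",
                        missing_label = 0.7, missing_geno = 0.1)
  )
  for (nm in names(specs)) {
    sim <- do.call(simulate_carriers,
                   c(specs[[nm]], list(seed = seed + match(nm, names(specs)))))
    out[[nm]] <- .write_fixture(sim, dir, nm)
  }
  out$qc_fail <- .write_qc_fixture(dir, seed + 100L)
  invisible(out)
}

.write_fixture <- function(sim, dir, name) {
  phen_path <- file.path(dir, paste0(name, "_phenotypes.tsv"))
  geno_path <- file.path(dir, paste0(name, "_genotypes.tsv"))
  truth_path <- file.path(dir, paste0(name, "_truth.txt"))
  utils::write.table(sim$phenotypes, phen_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  write_dosage_tsv(sim$genotypes, geno_path)
  cfg <- sim$truth$config
  keys <- vapply(names(cfg), function(k)
    paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1))
  writeLines(keys, truth_path)
  list(phenotypes = phen_path, genotypes = geno_path, truth = truth_path)
}

.write_qc_fixture <- function(dir, seed) {
  sim <- simulate_carriers(n_families = 250, family_size = 2, hr = 1.0,
                           n_null_snps = 5, seed = seed)
  n <- ncol(sim$genotypes$dosages)
  ids <- colnames(sim$genotypes$dosages)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed + 1L)
  # planted failures, built deterministically
  low_call <- stats::rbinom(n, 2L, 0.3)
  low_call[seq_len(ceiling(n * 0.06))] <- NA_integer_    # call rate 0.94
  hwe_fail <- rep(c(0L, 2L), length.out = n)             # no heterozygotes
  rare <- integer(n); rare[seq_len(round(0.04 * n))] <- 1L  # maf 0.02
  dos <- rbind(sim$genotypes$dosages, low_call = low_call,
               hwe_fail = hwe_fail, rare = rare)
  variants <- rbind(sim$genotypes$variants,
                    data.frame(snp_id = c("low_call", "hwe_fail", "rare"),
                               chrom = "1", pos = c(9e5, 9.1e5, 9.2e5),
                               ref = "A", eff = "G"))
  gm <- genotype_matrix(dos, variants)
  sim$genotypes <- gm
  paths <- .write_fixture(sim, dir, "qc_fail")
  cat("planted_failures=low_call,hwe_fail,rare\n",
      file = paths$truth, append = TRUE)
  paths
}
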