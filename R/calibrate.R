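#' Hardy-Weinberg genotype prior
#'
#' Genotype probabilities ((1-q)^2, 2q(1-q), q^2) for effect-allele
#' frequency `q`, used as the genotype prior of the retrospective
#' likelihood.
#'
#' @param q Effect-allele frequency, strictly inside (0, 1).
#' @return List with elements `q` and `p` (length-3 probability vector for
#'   dosages 0, 1, 2).
#' @examples
#' hwe_priors(0.3)$p  # 0.49 0.42 0.09
#' @export
hwe_priors <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop("allele frequency q must lie strictly in (0, 1)")
  list(q = q, p = c((1 - q)^2, 2 * q * (1 - q), q^2))
}

#' Calibrate baseline hazards to a carrier incidence curve
#'
#' The model gives carrier `i` with genotype dosage `z` the yearly
#' breast-cancer hazard `sum_s lambda0_s(t) exp(beta_s z)` decomposed over
#' `S` tumor subtypes.  The baselines `lambda0_s(t)` are not free
#' parameters: at every age they are pinned so that (a) the
#' genotype-averaged incidence among women still at risk equals the
#' external carrier incidence `mu(t)` and (b) the genotype-averaged share
#' of subtype `s` among incident cases equals the subtype mixture
#' `f_s(t)`.  Both constraints have the closed-form recursive solution
#' implemented here:
#' `lambda0_s(t) = f_s(t) mu(t) * sum_g p_g S(t|g) / sum_g p_g S(t|g) e^{beta_s z_g}`
#' with survivor functions `S(t|g)` accumulated from earlier ages.
#'
#' With a single outcome (`S = 1`, `f = 1`) this reduces to the overall
#' breast-cancer calibration; at `beta = 0` it returns
#' `lambda0_s(t) = f_s(t) mu(t)` exactly.
#'
#' @param beta Numeric vector of per-allele log hazard ratios, one per
#'   subtype (a scalar for the single-outcome model).
#' @param q Effect-allele frequency for the HWE prior (or a list from
#'   [hwe_priors()]).
#' @param incidence Incidence curve: a data frame with `age`/`rate`
#'   columns covering the grid, or a rate vector on the grid.
#' @param ages Integer age grid (default 18:80).
#' @param f Subtype mixture proportions: vector of length `S` (constant in
#'   age) or an `S x length(ages)` matrix with unit column sums.  Defaults
#'   to 1 when `beta` is scalar.
#' @return An `S x length(ages)` matrix of baseline hazards, with the age
#'   grid in `dimnames` and the maximum absolute calibration residual in
#'   attribute `residual`.
#' @examples
#' lam <- calibrate_baseline(log(2), 0.3, default_incidence("BRCA1"))
#' attr(lam, "residual") < 1e-10
#' @export
calibrate_baseline <- function(beta, q, incidence, ages = 18:80, f = NULL) {
  if (any(!is.finite(beta))) stop("beta must be finite")
  prior <- if (is.list(q)) q else hwe_priors(q)
  S <- length(beta)
  nA <- length(ages)
  mu <- .incidence_on_grid(incidence, ages)
  if (is.null(f)) {
    if (S != 1L) stop("subtype proportions f are required when length(beta) > 1")
    f <- matrix(1, 1L, nA)
  } else if (is.null(dim(f))) {
    if (length(f) != S) stop("f must have one proportion per subtype")
    f <- matrix(f, S, nA)
  }
  if (!isTRUE(all.equal(colSums(f), rep(1, nA), tolerance = 1e-8)))
    stop("subtype proportions f must sum to 1 at every age")
  z <- 0:2
  E <- exp(outer(beta, z))            # S x 3
  surv <- rep(1, 3)                   # S(t | g), survival to start of age t
  lam <- matrix(NA_real_, S, nA, dimnames = list(NULL, ages))
  resid <- 0
  for (a in seq_len(nA)) {
    w <- prior$p * surv
    denom <- as.vector(E %*% w)       # sum_g p_g S e^{beta_s z_g}, per s
    lam[, a] <- f[, a] * mu[a] * sum(w) / denom
    if (any(!is.finite(lam[, a])) || any(lam[, a] < 0))
      stop("non-finite baseline hazard at age ", ages[a])
    h_g <- as.vector(crossprod(lam[, a, drop = FALSE], E))  # total hazard per g
    # conservation check: genotype-averaged incidence equals mu(t)
    resid <- max(resid, abs(sum(w * h_g) - mu[a] * sum(w)))
    surv <- surv * exp(-h_g)
  }
  attr(lam, "residual") <- resid
  attr(lam, "ages") <- as.integer(ages)
  lam
}

#' @rdname calibrate_baseline
#' @export
calibrate_subtype_baselines <- function(beta, f, q, incidence, ages = 18:80) {
  calibrate_baseline(beta, q, incidence, ages = ages, f = f)
}

# Per-age log-likelihood tables for every (genotype, outcome) combination.
#
# Returns, on the grid `ages`:
#   lam       S x nA calibrated baselines
#   log_cens  3 x nA  log P(no event through the year of age t | g)
#   log_event 3 x nA  log P(first event during the year of age t | g)
#   log_share 3 x nA x S  log P(subtype s | event at t, g)
.grid_tables <- function(beta, q, f, incidence, ages) {
  lam <- calibrate_baseline(beta, q, incidence, ages = ages, f = f)
  S <- nrow(lam); nA <- ncol(lam)
  z <- 0:2
  E <- exp(outer(beta, z))                     # S x 3
  log_cens <- matrix(NA_real_, 3L, nA)
  log_event <- matrix(NA_real_, 3L, nA)
  log_share <- array(NA_real_, c(3L, nA, S))
  for (gi in 1:3) {
    hs <- lam * E[, gi]                        # S x nA subtype hazards
    H <- .colSums(hs, S, nA)                   # total yearly hazard
    cumH <- cumsum(H)
    logS_to <- c(0, cumH[-nA])                 # -log S(t|g) at year start
    log_cens[gi, ] <- -cumH
    log_event[gi, ] <- -logS_to + log(-expm1(-H))
    for (s in seq_len(S)) log_share[gi, , s] <- log(hs[s, ]) - log(H)
  }
  list(lam = lam, log_cens = log_cens, log_event = log_event,
       log_share = log_share, prior = if (is.list(q)) q else hwe_priors(q),
       ages = as.integer(ages), S = S)
}

# log P(phenotype | g) for records indexed on the grid.
# t_idx: index into ages; d: 0/1; s_idx: subtype 1..S or NA.
.phenotype_loglik <- function(tab, t_idx, d, s_idx) {
  n <- length(t_idx)
  out <- matrix(NA_real_, n, 3L)
  for (gi in 1:3) {
    v <- ifelse(d == 1L, tab$log_event[gi, t_idx], tab$log_cens[gi, t_idx])
    lab <- d == 1L & !is.na(s_idx)
    if (any(lab))
      v[lab] <- v[lab] + tab$log_share[cbind(gi, t_idx[lab], s_idx[lab])]
    out[, gi] <- v
  }
  out
}

# log posterior P(g | phenotype): rows sum to one on the probability scale.
.log_posterior <- function(tab, t_idx, d, s_idx) {
  lp <- .phenotype_loglik(tab, t_idx, d, s_idx)
  lp <- sweep(lp, 2L, log(tab$prior$p), "+")
  m <- apply(lp, 1L, max)
  lp - (m + log(rowSums(exp(lp - m))))
}

# log P(g, s | t, d): the subtype label is part of the outcome, so the
# normalization marginalizes it (conditions on the disease phenotype only).
# Returns the n x 3 matrix of joint log-contributions per genotype.
.log_joint <- function(tab, t_idx, d, s_idx) {
  lp_full <- .phenotype_loglik(tab, t_idx, d, s_idx)
  lp_marg <- .phenotype_loglik(tab, t_idx, d, rep(NA_integer_, length(t_idx)))
  lp_marg <- sweep(lp_marg, 2L, log(tab$prior$p), "+")
  m <- apply(lp_marg, 1L, max)
  denom <- m + log(rowSums(exp(lp_marg - m)))
  sweep(lp_full, 2L, log(tab$prior$p), "+") - denom
}

#' Genotype posterior given a carrier's phenotype
#'
#' The building block of the retrospective likelihood:
#' `P(g | phenotype) ∝ p_g L(phenotype | g)`, where for an unaffected
#' carrier censored at age `t` the phenotype likelihood is survival through
#' the year of age `t`, and for a carrier affected at age `t` it is
#' survival to `t` times the within-year event probability
#' `1 - exp(-hazard)` (times the subtype share when a label is present).
#' At `beta = 0` the likelihood no longer depends on the genotype and the
#' posterior equals the HWE prior.
#'
#' @param t Integer age(s) at event or censoring, on the grid.
#' @param d Event indicator(s), 0/1.
#' @param s Integer subtype index in `1..S`, or `NA` (must be `NA` when
#'   `d = 0`).
#' @param beta,q,incidence,ages,f Model parameters as in
#'   [calibrate_baseline()].
#' @return Matrix of posterior probabilities, one row per record, columns
#'   for dosages 0, 1, 2; each row sums to 1.
#' @export
retro_posterior <- function(t, d, s = NA, beta, q, incidence,
                            ages = 18:80, f = NULL) {
  t_idx <- match(t, ages)
  if (anyNA(t_idx)) stop("age(s) outside the analysis grid: ",
                         paste(unique(t[is.na(t_idx)]), collapse = ", "))
  n <- length(t_idx)
  d <- rep_len(as.integer(d), n)
  s_idx <- rep_len(as.integer(s), n)
  if (any(d == 0L & !is.na(s_idx)))
    stop("subtype labels are only defined for affected carriers")
  tab <- .grid_tables(beta, q, f, incidence, ages)
  if (any(!is.na(s_idx) & (s_idx < 1L | s_idx > tab$S)))
    stop("subtype index outside 1..S")
  exp(.log_posterior(tab, t_idx, d, s_idx))
}

#' Retrospective log-likelihood of a cohort
#'
#' Sum over carriers of the log-probability of the observed genotype -
#' and, in the subtype model, the observed tumor-subtype label -
#' conditional on the disease phenotype: `log P(g_i, s_i | t_i, d_i)`.
#' The label is part of the outcome, so the normalization marginalizes
#' over it; for the single-outcome model this is exactly
#' `log P(g_i | phenotype_i)`.  Carriers with a
#' missing dosage are excluded (their count is reported in the
#' `n_dropped` attribute).  When `survival$stratum` has several levels and
#' `incidence` is a named list, each stratum is calibrated against its own
#' curve.
#'
#' @param survival Data frame from [derive_survival()]; the subtype factor
#'   `s` (if any) defines the label indices.
#' @param dosage Integer vector of effect-allele counts per carrier.
#' @param beta,q,f,ages As in [calibrate_baseline()].
#' @param incidence A single curve, or a named list of curves by stratum.
#' @return The log-likelihood (scalar), with attribute `n_dropped`.
#' @export
cohort_loglik <- function(survival, dosage, beta, q, incidence,
                          ages = 18:80, f = NULL) {
  prep <- .prep_cohort(survival, dosage, ages)
  if (!prep$n) stop("no usable carriers (all dosages missing?)")
  ll <- .cohort_loglik_prepped(prep, beta, q, incidence, ages, f)
  structure(sum(ll), n_dropped = prep$n_dropped)
}

# Shared data preparation: grid indexing, label indexing, missing-dosage drop.
.prep_cohort <- function(survival, dosage, ages) {
  g <- as.integer(dosage)
  if (any(!is.na(g) & !g %in% 0:2)) stop("dosages must be 0, 1, 2 or NA")
  keep <- !is.na(g)
  sv <- survival[keep, , drop = FALSE]
  t_idx <- match(sv$t, ages)
  if (anyNA(t_idx)) stop("event/censoring age(s) outside the analysis grid")
  s_col <- sv[["s"]]   # exact: `$` would partial-match the stratum column
  s_fac <- if (is.null(s_col)) factor(rep(NA_character_, nrow(sv)))
           else if (is.factor(s_col)) s_col   # keep declared levels
           else factor(s_col)
  s_idx <- as.integer(s_fac)
  if (any(sv$d == 0L & !is.na(s_idx)))
    stop("subtype labels present on unaffected carriers")
  if (any(!sv$d %in% 0:1)) stop("event indicator d must be 0 or 1")
  list(n = nrow(sv), n_dropped = sum(!keep), g = g[keep],
       t_idx = t_idx, d = as.integer(sv$d), s_idx = s_idx,
       levels = levels(s_fac),
       family = if (!is.null(sv$family_id)) as.character(sv$family_id)
                else as.character(seq_len(nrow(sv))),
       stratum = if (!is.null(sv$stratum)) as.character(sv$stratum)
                 else rep("all", nrow(sv)))
}

# Per-carrier log posterior at the observed dosage; stratum-aware.
.cohort_loglik_prepped <- function(prep, beta, q, incidence, ages, f) {
  out <- numeric(prep$n)
  strata <- if (is.list(incidence) && !is.data.frame(incidence))
    split(seq_len(prep$n), prep$stratum) else list(all = seq_len(prep$n))
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    inc <- if (is.list(incidence) && !is.data.frame(incidence)) {
      if (is.null(incidence[[nm]])) stop("no incidence curve for stratum ", nm)
      incidence[[nm]]
    } else incidence
    tab <- .grid_tables(beta, q, f, inc, ages)
    if (any(!is.na(prep$s_idx) & prep$s_idx > tab$S))
      stop("subtype label index outside 1..S")
    lp <- .log_joint(tab, prep$t_idx[idx], prep$d[idx], prep$s_idx[idx])
    out[idx] <- lp[cbind(seq_along(idx), prep$g[idx] + 1L)]
  }
  out
}
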