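#' Fit the retrospective-likelihood hazard model for one SNP
#'
#' Maximum-likelihood estimation of per-allele log hazard ratios under the
#' carrier model `lambda(t | z) = lambda0(t) exp(beta z)` (one `beta` per
#' tumor subtype in the competing-risk extension), where the likelihood is
#' the probability of each carrier's genotype conditional on her disease
#' phenotype.  This conditioning removes the bias induced by
#' outcome-dependent ascertainment of carrier cohorts.  The baseline
#' hazards are recalibrated to the external carrier incidence curve at
#' every trial value of the parameters (a profile construction, see
#' [calibrate_baseline()]), and the allele frequency `q` of the genotype
#' prior is by default estimated jointly with `beta`.
#'
#' Affected carriers with a missing subtype label contribute the
#' label-marginalized likelihood (missing-at-random assumption); carriers
#' with a missing dosage are excluded from this SNP's fit.  Variances are
#' reported both model-based (inverse observed information) and robust,
#' using a sandwich estimator with score contributions summed within
#' families to account for the non-independence of relatives.
#'
#' @param survival Data frame from [derive_survival()].  The factor column
#'   `s` (subtype label of affected carriers, `NA` allowed) determines the
#'   number of subtypes; with no labels a single-outcome model is fitted.
#' @param dosage Integer vector of effect-allele counts (0/1/2, `NA`
#'   for failed calls), aligned with `survival` rows.
#' @param incidence Carrier incidence curve (data frame with `age`,
#'   `rate`), or a named list of curves by stratum; defaults to
#'   [default_incidence()] for the cohort's gene.
#' @param q `"mle"` (joint estimation, default), `"plugin"` (effect-allele
#'   frequency of the observed dosages), or a fixed numeric frequency.
#' @param f Subtype mixture proportions (length-S vector or S x ages
#'   matrix); defaults to the observed proportions among labeled cases,
#'   constant in age.
#' @param ages Integer analysis age grid (default 18:80).
#' @param control List of optimizer settings: `maxit` (default 500),
#'   `grad_tol` (infinity-norm tolerance for the final gradient check,
#'   default 1e-2), `step` (central-difference step for score
#'   contributions, default 1e-5).
#' @return An object of class `carrier_fit` with components `beta`, `hr`,
#'   `q`, `f`, `vcov_robust`, `vcov_model`, `se_robust`, `se_model`,
#'   `loglik`, `n_used`, `n_events`, `n_dropped`, `scores`, `baseline`,
#'   `heterogeneity` (for S > 1), `separation`, `inestimable` and
#'   `convergence`.  Methods: [print()], [summary()], [coef()], [vcov()],
#'   [confint()], [logLik()], [predict()], [residuals()], [simulate()],
#'   [plot()].
#' @examples
#' sim <- simulate_carriers(n_families = 300, maf = 0.3, hr = 1.4, seed = 1)
#' sv <- derive_survival(sim$phenotypes)
#' fit <- carrier_fit(sv, sim$genotypes$dosages["causal", ])
#' summary(fit)
#' @export
carrier_fit <- function(survival, dosage, incidence = NULL,
                        q = c("mle", "plugin"), f = NULL, ages = 18:80,
                        control = list()) {
  ctl <- modifyList(list(maxit = 500, grad_tol = 1e-2, step = 1e-5,
                         reltol = 1e-12), control)
  prep <- .prep_cohort(survival, dosage, ages)
  if (!prep$n) stop("no usable carriers (all dosages missing?)")
  if (sum(prep$d) < 1L) stop("at least one breast-cancer event is required")
  incidence <- .resolve_incidence(incidence, survival, ages)

  S <- max(1L, length(prep$levels))
  lev <- if (S > 1L) prep$levels else "overall"
  # subtype mixture from labeled cases unless supplied
  counts <- if (S > 1L)
    tabulate(prep$s_idx[prep$d == 1L & !is.na(prep$s_idx)], nbins = S)
  else sum(prep$d)
  if (is.null(f)) {
    f <- if (S > 1L) {
      if (sum(counts) == 0L) stop("no labeled events to estimate subtype proportions")
      counts / sum(counts)
    } else NULL
  }
  inestimable <- stats::setNames(if (S > 1L) counts == 0L
                                 else rep(FALSE, S), lev)
  if (any(inestimable))
    warning("no labeled events for subtype(s): ",
            paste(lev[inestimable], collapse = ", "), "; flagged inestimable")

  # separation: every event carries the same genotype
  g_events <- prep$g[prep$d == 1L]
  separation <- length(unique(g_events)) < 2L || length(unique(prep$g)) < 2L

  plugin_q <- min(max(mean(prep$g) / 2, 1e-3), 1 - 1e-3)
  est_q <- FALSE
  if (is.character(q)) {
    q <- match.arg(q)
    est_q <- q == "mle"
    q0 <- plugin_q
  } else {
    stopifnot(is.numeric(q), q > 0, q < 1)
    q0 <- q
  }

  free <- which(!inestimable)
  npar_b <- length(free)
  theta0 <- c(rep(0, npar_b), if (est_q) stats::qlogis(q0))
  unpack <- function(theta) {
    beta <- numeric(S)
    beta[free] <- theta[seq_len(npar_b)]
    q <- if (est_q) stats::plogis(theta[npar_b + 1L]) else q0
    list(beta = beta, q = min(max(q, 1e-12), 1 - 1e-12))
  }
  percarrier <- function(theta) {
    par <- unpack(theta)
    .cohort_loglik_prepped(prep, par$beta, par$q, incidence, ages, f)
  }
  negll <- function(theta) -sum(percarrier(theta))

  if (separation) {
    warning("separation: all events share one genotype; no estimate")
    na_v <- stats::setNames(rep(NA_real_, S), lev)
    na_m <- matrix(NA_real_, S, S, dimnames = list(lev, lev))
    return(structure(list(
      beta = na_v, hr = na_v, q = q0, q_estimated = est_q, f = f,
      subtypes = lev, S = S, vcov_robust = na_m, vcov_model = na_m,
      se_robust = na_v, se_model = na_v, loglik = NA_real_,
      n_used = prep$n,
      n_events = if (S > 1L) stats::setNames(counts, lev) else c(overall = sum(prep$d)),
      n_dropped = prep$n_dropped,
      n_families = length(unique(prep$family)),
      incidence = incidence, ages = as.integer(ages),
      heterogeneity = NULL, separation = TRUE, inestimable = inestimable,
      convergence = NULL, call = match.call()), class = "carrier_fit"))
  }

  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  if (opt$convergence != 0L)
    stop("optimizer failed to converge (code ", opt$convergence,
         ") at theta = ", paste(signif(opt$par, 6), collapse = ", "))
  grad <- .num_grad(negll, opt$par, ctl$step)
  if (max(abs(grad)) > ctl$grad_tol) {  # polish once from the first optimum
    opt <- stats::optim(opt$par, negll, method = "BFGS",
                        control = list(maxit = ctl$maxit, reltol = ctl$reltol))
    grad <- .num_grad(negll, opt$par, ctl$step)
    if (max(abs(grad)) > ctl$grad_tol)
      stop("no convergence: gradient infinity-norm ", signif(max(abs(grad)), 3),
           " at theta = ", paste(signif(opt$par, 6), collapse = ", "))
  }
  theta_hat <- opt$par
  par_hat <- unpack(theta_hat)

  info <- stats::optimHess(theta_hat, negll)
  scores <- .score_matrix(percarrier, theta_hat, ctl$step)
  vc <- .sandwich(scores, prep$family, info)
  pidx <- seq_len(npar_b)

  beta <- stats::setNames(rep(NA_real_, S), lev)
  beta[free] <- theta_hat[pidx]
  se_r <- se_m <- stats::setNames(rep(NA_real_, S), lev)
  vr <- vm <- matrix(NA_real_, S, S, dimnames = list(lev, lev))
  vr[free, free] <- vc$robust[pidx, pidx, drop = FALSE]
  vm[free, free] <- vc$model[pidx, pidx, drop = FALSE]
  se_r[free] <- sqrt(diag(vr)[free])
  se_m[free] <- sqrt(diag(vm)[free])

  if (separation) beta[] <- NA_real_

  het <- if (S > 1L && sum(!inestimable) > 1L && !separation)
    heterogeneity_test(beta[free], vr[free, free, drop = FALSE]) else NULL

  n_events <- if (S > 1L) {
    ev <- stats::setNames(counts, lev)
    c(ev, unlabeled = sum(prep$d == 1L & is.na(prep$s_idx)))
  } else c(overall = sum(prep$d))

  structure(list(
    beta = beta, hr = exp(beta), q = par_hat$q, q_estimated = est_q,
    f = f, subtypes = lev, S = S,
    vcov_robust = vr, vcov_model = vm,
    se_robust = se_r, se_model = se_m,
    vcov_full_robust = vc$robust, vcov_full_model = vc$model,
    loglik = -opt$value, n_used = prep$n, n_events = n_events,
    n_dropped = prep$n_dropped, n_families = length(unique(prep$family)),
    scores = scores, family = prep$family,
    baseline = calibrate_baseline(ifelse(is.na(beta), 0, beta), par_hat$q,
                                  if (is.list(incidence) && !is.data.frame(incidence))
                                    incidence[[1L]] else incidence,
                                  ages = ages, f = f),
    incidence = incidence, ages = as.integer(ages),
    heterogeneity = het, separation = separation, inestimable = inestimable,
    convergence = list(iterations = opt$counts[["function"]],
                       grad_norm = max(abs(grad))),
    call = match.call()), class = "carrier_fit")
}

.resolve_incidence <- function(incidence, survival, ages) {
  if (!is.null(incidence)) return(incidence)
  gene <- unique(as.character(survival$gene))
  if (length(gene) != 1L)
    stop("cohort spans several genes; supply an incidence curve explicitly")
  default_incidence(gene, ages)
}

.num_grad <- function(fn, theta, h) {
  vapply(seq_along(theta), function(j) {
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    (fn(up) - fn(dn)) / (2 * h)
  }, numeric(1))
}

# n x p matrix of per-carrier score contributions (central differences
# through the recalibrated baseline).
.score_matrix <- function(percarrier, theta, h) {
  p <- length(theta)
  out <- matrix(NA_real_, length(percarrier(theta)), p)
  for (j in seq_len(p)) {
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    out[, j] <- (percarrier(up) - percarrier(dn)) / (2 * h)
  }
  out
}

.sandwich <- function(scores, family, info) {
  A_inv <- tryCatch(solve(info), error = function(e)
    stop("observed information is singular"))
  fam_scores <- rowsum(scores, family)
  B <- crossprod(fam_scores)
  robust <- A_inv %*% B %*% A_inv
  list(model = (A_inv + t(A_inv)) / 2, robust = (robust + t(robust)) / 2)
}

#' Family-clustered sandwich covariance
#'
#' `A^-1 B A^-1` with `A` the observed information and
#' `B = sum_f (sum_{i in f} U_i)(sum_{i in f} U_i)^T`, score contributions
#' summed within families.  With singleton families this is the ordinary
#' per-individual sandwich.
#'
#' @param scores Numeric matrix of per-carrier score contributions
#'   (carriers x parameters).
#' @param family Family identifier per carrier.
#' @param information Observed information matrix (negative Hessian of the
#'   log-likelihood).
#' @return The robust covariance matrix.
#' @export
robust_covariance <- function(scores, family, information) {
  scores <- as.matrix(scores)
  .sandwich(scores, family, information)$robust
}

#' Score test of no association (beta = 0)
#'
#' Per-carrier score contributions `U_i` are the derivative of the
#' retrospective log-likelihood at `beta = 0` (central difference through
#' the recalibrated baseline); the variance sums squared within-family
#' score totals, so the test is robust to family clustering.  The
#' statistic `U^2 / V` is referred to chi-square with 1 df.
#'
#' @inheritParams carrier_fit
#' @param q Allele frequency of the genotype prior; default is the
#'   plug-in effect-allele frequency of the observed dosages.
#' @return List with `statistic`, `df`, `p_value`, `U`, `V`, `n_used`.
#' @export
score_test <- function(survival, dosage, incidence = NULL, q = NULL,
                       ages = 18:80, control = list()) {
  ctl <- modifyList(list(step = 1e-5), control)
  prep <- .prep_cohort(survival, dosage, ages)
  if (!prep$n) stop("no usable carriers")
  incidence <- .resolve_incidence(incidence, survival, ages)
  if (is.null(q)) q <- min(max(mean(prep$g) / 2, 1e-3), 1 - 1e-3)
  prep1 <- prep; prep1$s_idx[] <- NA_integer_; prep1$levels <- character()
  h <- ctl$step
  U_i <- (.cohort_loglik_prepped(prep1, +h, q, incidence, ages, NULL) -
          .cohort_loglik_prepped(prep1, -h, q, incidence, ages, NULL)) / (2 * h)
  fam <- rowsum(U_i, prep$family)
  U <- sum(U_i)
  V <- sum(fam^2)
  if (V <= 0)
    stop("score variance is zero (constant dosage?); test undefined")
  stat <- U^2 / V
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1L, lower.tail = FALSE),
       U = U, V = V, n_used = prep$n)
}

#' Wald test of subtype heterogeneity
#'
#' Tests equality of the subtype-specific log hazard ratios using the
#' `S - 1` contrasts `beta_s - beta_S` and their robust covariance; the
#' statistic is chi-square with `S - 1` df.  For two subtypes it reduces
#' to `(beta1 - beta2)^2 / (v11 + v22 - 2 v12)`.
#'
#' @param beta Vector of subtype log hazard ratios, or a `carrier_fit`.
#' @param vcov Covariance matrix of `beta` (ignored for a fit object,
#'   which uses its robust covariance).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
heterogeneity_test <- function(beta, vcov = NULL) {
  if (inherits(beta, "carrier_fit")) {
    ok <- !is.na(beta$beta)
    vcov <- beta$vcov_robust[ok, ok, drop = FALSE]
    beta <- beta$beta[ok]
  }
  S <- length(beta)
  if (S < 2L) stop("heterogeneity requires at least two subtypes")
  if (!isTRUE(all.equal(dim(vcov), c(S, S))))
    stop("vcov must be ", S, " x ", S)
  C <- cbind(diag(S - 1L), -1)
  d <- C %*% beta
  V <- C %*% vcov %*% t(C)
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular contrast covariance; heterogeneity test undefined"))
  stat <- drop(t(d) %*% Vi %*% d)
  list(statistic = stat, df = S - 1L,
       p_value = stats::pchisq(stat, S - 1L, lower.tail = FALSE))
}

#' Uncorrected prospective fit (comparator)
#'
#' Maximizes the ordinary prospective likelihood `P(phenotype | g)` with
#' the baseline hazard held at the population carrier incidence curve,
#' i.e. ignoring both the outcome-dependent ascertainment of the cohort
#' and the genotype-averaging constraint.  Provided as the comparator that
#' demonstrates the ascertainment bias the retrospective likelihood
#' removes; it is not a recommended estimator.
#'
#' @inheritParams carrier_fit
#' @return List with `beta`, `hr`, `se`, `loglik`, `n_used`.
#' @export
prospective_fit <- function(survival, dosage, incidence = NULL,
                            ages = 18:80) {
  prep <- .prep_cohort(survival, dosage, ages)
  if (!prep$n) stop("no usable carriers")
  incidence <- .resolve_incidence(incidence, survival, ages)
  mu <- .incidence_on_grid(if (is.list(incidence) && !is.data.frame(incidence))
    incidence[[1L]] else incidence, ages)
  t_idx <- prep$t_idx; d <- prep$d; g <- prep$g
  ll <- function(beta) {
    out <- numeric(3)
    for (gi in 1:3) {
      H <- mu * exp(beta * (gi - 1L))
      cumH <- cumsum(H)
      logS_to <- c(0, cumH[-length(H)])
      cens <- -cumH
      ev <- -logS_to + log(-expm1(-H))
      v <- ifelse(d == 1L, ev[t_idx], cens[t_idx])
      out[gi] <- sum(v[g == gi - 1L])
    }
    sum(out)
  }
  opt <- stats::optimize(function(b) -ll(b), c(-3, 3), tol = 1e-9)
  h <- 1e-4
  info <- -(ll(opt$minimum + h) - 2 * ll(opt$minimum) + ll(opt$minimum - h)) / h^2
  list(beta = opt$minimum, hr = exp(opt$minimum),
       se = if (info > 0) 1 / sqrt(info) else NA_real_,
       loglik = -opt$objective, n_used = prep$n)
}
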