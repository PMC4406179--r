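#' @export
print.carrier_fit <- function(x, digits = 3, ...) {
  cat("Retrospective-likelihood carrier hazard model\n")
  cat(sprintf("  n = %d carriers (%d families), %d dropped for missing dosage\n",
              x$n_used, x$n_families, x$n_dropped))
  cat("  events:", paste(names(x$n_events), x$n_events, collapse = ", "), "\n")
  if (x$separation) {
    cat("  separation: all events share one genotype; no estimate\n")
    return(invisible(x))
  }
  est <- cbind(HR = x$hr,
               lo = exp(x$beta - 1.959964 * x$se_robust),
               hi = exp(x$beta + 1.959964 * x$se_robust))
  rownames(est) <- x$subtypes
  print(round(est, digits))
  cat(sprintf("  q-hat = %.4f (%s), logLik = %.2f\n", x$q,
              if (x$q_estimated) "joint MLE" else "fixed/plug-in", x$loglik))
  if (!is.null(x$heterogeneity))
    cat(sprintf("  heterogeneity: chi2(%d) = %.3f, P_het = %.3g\n",
                x$heterogeneity$df, x$heterogeneity$statistic,
                x$heterogeneity$p_value))
  invisible(x)
}

#' @export
summary.carrier_fit <- function(object, ...) {
  z <- object$beta / object$se_robust
  tab <- data.frame(
    beta = object$beta, HR = object$hr,
    se_robust = object$se_robust, se_model = object$se_model,
    ci_low = exp(object$beta - 1.959964 * object$se_robust),
    ci_high = exp(object$beta + 1.959964 * object$se_robust),
    p = 2 * stats::pnorm(-abs(z)),
    row.names = object$subtypes)
  out <- list(coefficients = tab, q = object$q, loglik = object$loglik,
              n_used = object$n_used, n_events = object$n_events,
              n_families = object$n_families,
              heterogeneity = object$heterogeneity,
              separation = object$separation,
              convergence = object$convergence)
  class(out) <- "summary.carrier_fit"
  out
}

#' @export
print.summary.carrier_fit <- function(x, digits = 4, ...) {
  cat("Retrospective-likelihood carrier hazard model\n\n")
  printCoefmat(as.matrix(x$coefficients), digits = digits,
               P.values = TRUE, has.Pvalue = TRUE, cs.ind = integer(),
               tst.ind = integer())
  cat(sprintf("\nn = %d (%d families); events: %s\n", x$n_used, x$n_families,
              paste(names(x$n_events), x$n_events, collapse = ", ")))
  cat(sprintf("q-hat = %.4f, logLik = %.2f\n", x$q, x$loglik))
  if (!is.null(x$heterogeneity))
    cat(sprintf("P_het (chi2, %d df) = %.3g\n", x$heterogeneity$df,
                x$heterogeneity$p_value))
  invisible(x)
}

#' @export
coef.carrier_fit <- function(object, ...) object$beta

#' @export
vcov.carrier_fit <- function(object, type = c("robust", "model"), ...) {
  switch(match.arg(type), robust = object$vcov_robust,
         model = object$vcov_model)
}

#' @export
logLik.carrier_fit <- function(object, ...) {
  structure(object$loglik, df = sum(!is.na(object$beta)) + object$q_estimated,
            nobs = object$n_used, class = "logLik")
}

#' @export
confint.carrier_fit <- function(object, parm, level = 0.95,
                                scale = c("hr", "beta"), ...) {
  scale <- match.arg(scale)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  lo <- object$beta - zq * object$se_robust
  hi <- object$beta + zq * object$se_robust
  out <- cbind(lower = lo, upper = hi)
  if (scale == "hr") out <- exp(out)
  rownames(out) <- object$subtypes
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Posterior genotype probabilities for carrier phenotypes
#'
#' @param object A [carrier_fit()].
#' @param newdata Survival data frame ([derive_survival()]); defaults to
#'   nothing (required).
#' @param type `"posterior"` for the 3-column probability matrix,
#'   `"dosage"` for the posterior mean dosage.
#' @param ... Unused.
#' @export
predict.carrier_fit <- function(object, newdata,
                                type = c("posterior", "dosage"), ...) {
  type <- match.arg(type)
  beta <- ifelse(is.na(object$beta), 0, object$beta)
  s_idx <- if (!is.null(newdata[["s"]]))
    as.integer(factor(newdata[["s"]], levels = object$subtypes))
  else rep(NA_integer_, nrow(newdata))
  inc <- if (is.list(object$incidence) && !is.data.frame(object$incidence))
    object$incidence[[1L]] else object$incidence
  post <- retro_posterior(newdata$t, newdata$d, s_idx, beta, object$q,
                          inc, ages = object$ages, f = object$f)
  if (type == "posterior") {
    colnames(post) <- 0:2
    post
  } else drop(post %*% (0:2))
}

#' @export
residuals.carrier_fit <- function(object, newdata, dosage, ...) {
  if (missing(newdata) || missing(dosage))
    stop("supply the survival records and dosages used in the fit")
  keep <- !is.na(dosage)
  dosage[keep] - predict(object, newdata[keep, , drop = FALSE], type = "dosage")
}

#' Simulate cohorts from a fitted carrier model
#'
#' Draws synthetic carrier cohorts from the fitted parameters (beta, q,
#' subtype mixture and incidence curve) via [simulate_carriers()].
#'
#' @param object A [carrier_fit()].
#' @param nsim Number of cohorts.
#' @param seed Integer seed (required for reproducibility).
#' @param n_families,family_size,... Passed to [simulate_carriers()].
#' @return A list of `nsim` simulation objects.
#' @export
simulate.carrier_fit <- function(object, nsim = 1, seed = NULL,
                                 n_families = 500, family_size = 1, ...) {
  if (is.null(seed)) stop("a seed is required")
  gene <- if (is.data.frame(object$incidence)) object$incidence$gene[1L] else "BRCA1"
  inc <- if (is.list(object$incidence) && !is.data.frame(object$incidence))
    object$incidence[[1L]] else object$incidence
  lapply(seq_len(nsim), function(i)
    simulate_carriers(n_families = n_families, family_size = family_size,
                      gene = gene, maf = min(object$q, 1 - object$q),
                      hr = exp(ifelse(is.na(object$beta), 0, object$beta)),
                      subtypes = if (object$S > 1L) object$subtypes else NULL,
                      f = object$f, incidence = inc,
                      seed = seed + i - 1L, ...))
}

#' @export
plot.carrier_fit <- function(x, ...) {
  ages <- x$ages
  inc <- if (is.list(x$incidence) && !is.data.frame(x$incidence))
    x$incidence[[1L]] else x$incidence
  mu <- .incidence_on_grid(inc, ages)
  lam <- x$baseline
  matplot(ages, t(lam), type = "l", lty = 1, col = seq_len(nrow(lam)) + 1,
          xlab = "age (years)", ylab = "yearly hazard",
          main = "Calibrated baseline hazards", ...)
  lines(ages, mu, lty = 2, col = 1)
  legend("topleft", bty = "n", lty = c(2, rep(1, nrow(lam))),
         col = c(1, seq_len(nrow(lam)) + 1),
         legend = c("carrier incidence mu(t)", x$subtypes))
  invisible(x)
}
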