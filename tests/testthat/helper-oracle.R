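# Independent scalar-loop oracles for the retrospective likelihood.
# Deliberately written as plain per-genotype / per-year loops, separate
# from the vectorized engine, so the two can cross-check each other.

oracle_hwe <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# baseline hazards solving the calibration constraints, scalar recursion
oracle_baselines <- function(beta, q, mu, f = 1) {
  S <- length(beta)
  f <- rep_len(f, S)
  p <- oracle_hwe(q)
  lam <- matrix(0, S, length(mu))
  surv <- c(1, 1, 1)
  for (a in seq_along(mu)) {
    for (s in seq_len(S)) {
      num <- den <- 0
      for (g in 0:2) {
        num <- num + p[g + 1] * surv[g + 1]
        den <- den + p[g + 1] * surv[g + 1] * exp(beta[s] * g)
      }
      lam[s, a] <- f[s] * mu[a] * num / den
    }
    for (g in 0:2) {
      H <- 0
      for (s in seq_len(S)) H <- H + lam[s, a] * exp(beta[s] * g)
      surv[g + 1] <- surv[g + 1] * exp(-H)
    }
  }
  lam
}

# P(phenotype | g) by direct year-by-year products
oracle_phen_prob <- function(t, d, s, beta, q, mu, ages, f = 1) {
  lam <- oracle_baselines(beta, q, mu, f)
  S <- length(beta)
  sapply(0:2, function(g) {
    surv <- 1
    for (a in seq_along(ages)) {
      H <- 0
      for (k in seq_len(S)) H <- H + lam[k, a] * exp(beta[k] * g)
      if (ages[a] < t) {
        surv <- surv * exp(-H)
      } else if (ages[a] == t) {
        if (d == 0) return(surv * exp(-H))
        mass <- surv * (1 - exp(-H))
        if (is.na(s)) return(mass)
        return(mass * lam[s, a] * exp(beta[s] * g) / H)
      }
    }
    stop("t beyond grid")
  })
}

oracle_posterior <- function(t, d, s, beta, q, mu, ages, f = 1) {
  pr <- oracle_hwe(q) * oracle_phen_prob(t, d, s, beta, q, mu, ages, f)
  pr / sum(pr)
}

# joint contribution log P(g, s | t, d): numerator keeps the label, the
# denominator marginalizes it
oracle_cohort_loglik <- function(sv, g, beta, q, mu, ages, f = 1) {
  s_idx <- if (!is.null(sv[["s"]])) as.integer(factor(sv$s))
           else rep(NA, nrow(sv))
  pg <- oracle_hwe(q)
  sum(sapply(seq_len(nrow(sv)), function(i) {
    num <- pg * oracle_phen_prob(sv$t[i], sv$d[i], s_idx[i], beta, q, mu,
                                 ages, f)
    den <- pg * oracle_phen_prob(sv$t[i], sv$d[i], NA, beta, q, mu, ages, f)
    log(num[g[i] + 1]) - log(sum(den))
  }))
}

# one-way random-effects ICC through R's ANOVA machinery
oracle_icc_aov <- function(x, y) {
  d <- data.frame(value = c(x, y), target = factor(rep(seq_along(x), 2)))
  ms <- anova(aov(value ~ target, data = d))[["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + ms[2])
}
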