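mu_b1 <- default_incidence("BRCA1")

test_that("retrospective posterior: beta = 0 gives the prior, rows sum to 1", {
  for (q in c(0.1, 0.3, 0.5)) {
    post <- retro_posterior(c(30, 45, 60, 80), c(1, 0, 1, 0), NA,
                            beta = 0, q = q, incidence = mu_b1)
    expect_equal(post, matrix(hwe_priors(q)$p, 4, 3, byrow = TRUE),
                 tolerance = 1e-14)
  }
  for (b in c(-1.2, -0.3, 0.4, 1.2)) for (q in c(0.05, 0.3, 0.45)) {
    post <- retro_posterior(c(25, 40, 55, 70, 80), c(1, 1, 0, 0, 1), NA,
                            beta = b, q = q, incidence = mu_b1)
    expect_equal(rowSums(post), rep(1, 5), tolerance = 1e-12)
  }
  expect_error(retro_posterior(17, 0, NA, 0, 0.3, mu_b1), "grid")
  expect_error(retro_posterior(40, 0, 1, 0.2, 0.3, mu_b1), "affected")
})

test_that("one-year toy posterior matches full enumeration", {
  # single age, mu = 0.02, q = 0.3, beta = log 2, affected carrier
  q <- 0.3; b <- log(2); mu1 <- 0.02
  lam0 <- mu1 / (0.49 + 0.42 * 2 + 0.09 * 4)
  pg <- hwe_priors(q)$p
  lik <- 1 - exp(-lam0 * 2^(0:2))          # hand enumeration of P(d=1|g)
  hand <- pg * lik / sum(pg * lik)
  post <- retro_posterior(18, 1, NA, b, q, mu1, ages = 18)
  expect_equal(drop(post), hand, tolerance = 1e-12)
  # unaffected flips the enrichment direction
  post0 <- retro_posterior(18, 0, NA, b, q, mu1, ages = 18)
  hand0 <- pg * exp(-lam0 * 2^(0:2)) / sum(pg * exp(-lam0 * 2^(0:2)))
  expect_equal(drop(post0), hand0, tolerance = 1e-12)
})

test_that("affected-carrier posterior mean dosage exceeds 2q and grows with beta", {
  ages <- 18:40
  mu <- mu_b1$rate[1:23]
  for (q in c(0.1, 0.3)) {
    last <- -Inf
    for (b in c(0.1, 0.4, 0.8, 1.2)) {
      post <- retro_posterior(35, 1, NA, b, q, mu, ages = ages)
      m <- sum(drop(post) * 0:2)
      expect_gt(m, 2 * q)
      expect_gt(m, last)          # monotone in beta
      last <- m
      expect_equal(drop(post),
                   oracle_posterior(35, 1, NA, b, q, mu, ages),
                   tolerance = 1e-12)
    }
  }
})

test_that("cohort log-likelihood: beta = 0 identity, additivity, oracle match", {
  set.seed(3)
  sv <- toy_survival(t = c(30, 42, 55, 61, 70, 80, 39, 47, 52, 66),
                     d = c(1, 1, 0, 1, 0, 0, 1, 0, 1, 0))
  g <- c(0L, 2L, 1L, 1L, 0L, 2L, 1L, 0L, 2L, 1L)
  q <- 0.3
  # beta = 0: phenotype-free, exactly sum log p_g
  ll0 <- cohort_loglik(sv, g, 0, q, mu_b1)
  expect_equal(as.numeric(ll0), sum(log(hwe_priors(q)$p[g + 1])))
  # duplication doubles
  ll <- cohort_loglik(sv, g, 0.35, q, mu_b1)
  ll2 <- cohort_loglik(rbind(sv, sv), c(g, g), 0.35, q, mu_b1)
  expect_equal(as.numeric(ll2), 2 * as.numeric(ll), tolerance = 1e-12)
  # enumeration oracle on the 10-carrier toy
  expect_equal(as.numeric(ll),
               oracle_cohort_loglik(sv, g, 0.35, q, mu_b1$rate, 18:80),
               tolerance = 1e-12)
  # missing dosages are dropped and counted
  g_na <- g; g_na[c(2, 5)] <- NA
  lln <- cohort_loglik(sv, g_na, 0.35, q, mu_b1)
  expect_equal(attr(lln, "n_dropped"), 2L)
  expect_error(cohort_loglik(sv, rep(NA_integer_, 10), 0, q, mu_b1),
               "no usable")
})

test_that("recoding the dosage to the other allele flips the estimate's sign", {
  sim <- simulate_carriers(n_families = 600, family_size = 2, maf = 0.3,
                           hr = 1.4, seed = 21)
  sv <- derive_survival(sim$phenotypes)
  g <- sim$genotypes$dosages["causal", ]
  f1 <- carrier_fit(sv, g)
  f2 <- carrier_fit(sv, 2L - g)
  expect_equal(unname(coef(f2)), -unname(coef(f1)), tolerance = 1e-4)
  expect_equal(f2$q, 1 - f1$q, tolerance = 1e-4)
  expect_equal(f2$se_robust, f1$se_robust, tolerance = 1e-3)
})

test_that("single-replicate recovery and Wald/score agreement on simulated data", {
  sim <- simulate_carriers(n_families = 1000, family_size = 2, maf = 0.3,
                           hr = 1.3, seed = 31)
  sv <- derive_survival(sim$phenotypes)
  g <- sim$genotypes$dosages["causal", ]
  fit <- carrier_fit(sv, g)
  expect_lt(abs(coef(fit) - log(1.3)), 3 * fit$se_robust)
  expect_equal(unname(fit$hr), exp(unname(fit$beta)))
  st <- score_test(sv, g)
  wald <- (coef(fit) / fit$se_robust)^2
  expect_lt(abs(st$statistic - wald) / wald, 0.15)
  # model object contracts
  expect_true(isSymmetric(vcov(fit)))
  expect_equal(dim(confint(fit)), c(1L, 2L))
  ci <- confint(fit, scale = "beta")
  expect_equal(unname(ci[1, 2] - ci[1, 1]),
               2 * 1.959964 * unname(fit$se_robust), tolerance = 1e-6)
  post <- predict(fit, sv)
  expect_equal(rowSums(post), rep(1, nrow(sv)), tolerance = 1e-10)
  res <- residuals(fit, sv, g)
  expect_lt(abs(mean(res)), 0.05)     # scores nearly centered at the MLE
  expect_s3_class(summary(fit), "summary.carrier_fit")
})

test_that("score test refuses a constant dosage", {
  sv <- toy_survival(t = c(40, 50, 60), d = c(1, 0, 1))
  expect_error(score_test(sv, c(1L, 1L, 1L), mu_b1), "undefined|constant")
})

test_that("robust covariance: clustering no-op, duplication algebra, PSD", {
  set.seed(4)
  n <- 60
  U <- cbind(rnorm(n), rnorm(n))
  A <- crossprod(matrix(rnorm(4), 2)) + diag(2)
  # singleton families: identical to the per-individual sandwich
  vs <- robust_covariance(U, paste0("i", 1:n), A)
  expect_equal(vs, solve(A) %*% crossprod(U) %*% solve(A), tolerance = 1e-12)
  # duplicating each carrier: own-family B doubles, same-family B quadruples
  U2 <- rbind(U, U)
  own <- robust_covariance(U2, c(paste0("a", 1:n), paste0("b", 1:n)), A)
  same <- robust_covariance(U2, c(paste0("f", 1:n), paste0("f", 1:n)), A)
  expect_equal(own, 2 * vs, tolerance = 1e-12)
  expect_equal(same, 4 * vs, tolerance = 1e-12)
  # positive semi-definiteness across random score sets and clusterings
  for (i in 1:200) {
    m <- matrix(rnorm(30 * 2), 30)
    fam <- sample(letters[1:10], 30, replace = TRUE)
    v <- robust_covariance(m, fam, A)
    expect_gte(min(eigen(v, symmetric = TRUE)$values), -1e-10)
  }
  expect_error(robust_covariance(U, rep("f", n), matrix(0, 2, 2)), "singular")
})

test_that("separation and degenerate cohorts are flagged, not estimated", {
  sv <- toy_survival(t = c(40, 45, 50, 60, 42, 58), d = c(1, 1, 0, 0, 1, 0))
  g <- c(2L, 2L, 0L, 1L, 2L, 0L)   # every event on g = 2
  expect_warning(fit <- carrier_fit(sv, g, incidence = mu_b1), "separation")
  expect_true(fit$separation)
  expect_true(all(is.na(fit$beta)))
  expect_error(carrier_fit(toy_survival(50, 0), 1L, incidence = mu_b1),
               "event")
})
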