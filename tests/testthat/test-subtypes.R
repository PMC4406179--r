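mu_b1 <- default_incidence("BRCA1")

toy_subtype_cohort <- function() {
  sv <- toy_survival(t = c(30, 42, 55, 61, 70, 80, 39, 47, 52, 66),
                     d = c(1, 1, 0, 1, 0, 0, 1, 0, 1, 1),
                     s = c("neg", "pos", NA, NA, NA, NA, "neg", NA, "pos", NA))
  list(sv = sv, g = c(0L, 2L, 1L, 1L, 0L, 2L, 1L, 0L, 2L, 1L))
}

test_that("equal subtype effects reduce to the single-outcome likelihood", {
  toy <- toy_subtype_cohort()
  f <- c(0.4, 0.6)
  single <- toy$sv; single$s <- NULL
  diffs <- sapply(c(-0.5, 0, 0.3, 0.8), function(b)
    as.numeric(cohort_loglik(toy$sv, toy$g, c(b, b), 0.3, mu_b1, f = f)) -
      as.numeric(cohort_loglik(single, toy$g, b, 0.3, mu_b1)))
  # labeled events contribute a beta-free log f_s each; constant across beta
  expect_lt(diff(range(diffs)), 1e-10)
  n_neg <- 2; n_pos <- 2
  expect_equal(diffs[1], n_neg * log(0.4) + n_pos * log(0.6),
               tolerance = 1e-10)

  # with every label deleted the subtype likelihood collapses exactly
  nolab <- toy$sv; nolab$s <- factor(rep(NA_character_, nrow(nolab)))
  for (b in c(-0.4, 0.6))
    expect_equal(as.numeric(cohort_loglik(nolab, toy$g, c(b, b), 0.3, mu_b1,
                                          f = f)),
                 as.numeric(cohort_loglik(single, toy$g, b, 0.3, mu_b1)),
                 tolerance = 1e-12)
})

test_that("ten-carrier subtype toy matches the enumeration oracle", {
  toy <- toy_subtype_cohort()
  f <- c(0.45, 0.55)
  beta <- c(0.5, -0.2)   # factor order: neg, pos
  ll <- cohort_loglik(toy$sv, toy$g, beta, 0.3, mu_b1, f = f)
  expect_equal(as.numeric(ll),
               oracle_cohort_loglik(toy$sv, toy$g, beta, 0.3, mu_b1$rate,
                                    18:80, f = f),
               tolerance = 1e-12)
  # posterior normalization holds with labels and with missing labels
  post <- retro_posterior(c(42, 42, 42), c(1, 1, 1), c(1L, 2L, NA),
                          beta, 0.3, mu_b1, f = f)
  expect_equal(rowSums(post), rep(1, 3), tolerance = 1e-12)
  # labels referencing more subtypes than the model has are rejected
  expect_error(cohort_loglik(toy$sv, toy$g, 0.1, 0.3, mu_b1),
               "outside 1..S")
})

test_that("relabeling subtypes permutes the estimates identically", {
  sim <- simulate_carriers(n_families = 700, family_size = 2, maf = 0.3,
                           hr = c(1.4, 1.0), seed = 51)
  sv <- derive_survival(sim$phenotypes, classification = "subtype")
  g <- sim$genotypes$dosages["causal", ]
  f1 <- carrier_fit(sv, g)
  sv2 <- sv
  # same labels, new names whose alphabetical order is reversed
  sv2$s <- factor(c(negative = "znegative",
                    positive = "apositive")[as.character(sv$s)])
  f2 <- carrier_fit(sv2, g)
  expect_equal(unname(f2$beta[c("znegative", "apositive")]),
               unname(f1$beta[c("negative", "positive")]), tolerance = 1e-6)
  expect_equal(f2$heterogeneity$statistic, f1$heterogeneity$statistic,
               tolerance = 1e-4)
})

test_that("with all labels observed the subtype fit agrees with the competing-censor fit", {
  sim <- simulate_carriers(n_families = 1500, family_size = 2, maf = 0.3,
                           hr = c(1.4, 1.0), missing_label = 0, seed = 61)
  sv <- derive_survival(sim$phenotypes, classification = "subtype")
  g <- sim$genotypes$dosages["causal", ]
  fs <- carrier_fit(sv, g)
  # treat "negative" (the null-subtype) events as censored at diagnosis;
  # the sub-outcome's incidence is the positive-subtype share of mu(t)
  sv1 <- sv
  sv1$d[sv$s %in% "negative"] <- 0L
  sv1$s <- NULL
  mu_pos <- default_incidence("BRCA1")
  mu_pos$rate <- mu_pos$rate * fs$f[2]   # f in level order (neg, pos)
  fc <- carrier_fit(sv1, g, incidence = mu_pos)
  expect_lt(abs(fs$beta[["positive"]] - coef(fc)[[1]]),
            2 * fs$se_robust[["positive"]])
})

test_that("deleting all labels reproduces the single-outcome fit", {
  sim <- simulate_carriers(n_families = 500, family_size = 2, maf = 0.3,
                           hr = c(1.3, 1.0), seed = 71)
  sv <- derive_survival(sim$phenotypes, classification = "subtype")
  g <- sim$genotypes$dosages["causal", ]
  nolab <- sv; nolab$s <- NULL
  f_single <- carrier_fit(nolab, g)
  sv_na <- sv; sv_na$s <- factor(rep(NA_character_, nrow(sv)))
  f_na <- carrier_fit(sv_na, g)
  expect_equal(unname(coef(f_na)), unname(coef(f_single)), tolerance = 1e-6)
})

test_that("subtype effects are recovered with 40% missing labels", {
  truth <- log(c(1.3, 1.0))
  reps <- sapply(1:12, function(i) {
    sim <- simulate_carriers(n_families = 1500, family_size = 2, maf = 0.3,
                             hr = c(1.3, 1.0), missing_label = 0.4,
                             seed = 800 + i)
    sv <- derive_survival(sim$phenotypes, classification = "subtype")
    carrier_fit(sv, sim$genotypes$dosages["causal", ])$beta[
      c("positive", "negative")]
  })
  for (k in 1:2)
    expect_lt(abs(mean(reps[k, ]) - truth[k]),
              3 * sd(reps[k, ]) / sqrt(ncol(reps)) + 0.01)
})

test_that("heterogeneity test: closed forms and the S = 3 quadratic form", {
  eq <- heterogeneity_test(c(0.3, 0.3), diag(2))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  two <- heterogeneity_test(c(0.3, 0.1), diag(2))
  expect_equal(two$statistic, 0.02)
  expect_equal(two$df, 1L)
  # S = 2 closed form with covariance
  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  b <- c(0.5, 0.2)
  expect_equal(heterogeneity_test(b, V)$statistic,
               (b[1] - b[2])^2 / (V[1, 1] + V[2, 2] - 2 * V[1, 2]))
  # S = 3 against an independently constructed generalized quadratic form
  set.seed(5)
  b3 <- c(0.4, 0.1, -0.2)
  A <- matrix(rnorm(9), 3); V3 <- crossprod(A) + diag(3)
  C <- rbind(c(1, 0, -1), c(0, 1, -1))
  brute <- drop(t(C %*% b3) %*% solve(C %*% V3 %*% t(C)) %*% (C %*% b3))
  h3 <- heterogeneity_test(b3, V3)
  expect_equal(h3$statistic, brute, tolerance = 1e-12)
  expect_equal(h3$df, 2L)
  expect_error(heterogeneity_test(c(1, 2), matrix(0, 2, 2)), "singular")
})

test_that("a subtype without labeled events is flagged inestimable", {
  sv <- toy_survival(t = c(40, 45, 50, 60, 42, 58, 44, 66),
                     d = c(1, 1, 0, 0, 1, 0, 1, 0),
                     s = c("pos", "pos", NA, NA, NA, NA, "pos", NA))
  sv$s <- factor(sv$s, levels = c("neg", "pos"))
  g <- c(2L, 0L, 0L, 1L, 1L, 0L, 1L, 2L)
  expect_warning(fit <- carrier_fit(sv, g, incidence = mu_b1,
                                    f = c(0.3, 0.7)),
                 "inestimable")
  expect_true(fit$inestimable[["neg"]] ||
              any(fit$inestimable))  # named per subtype level
  expect_true(is.na(fit$beta[["neg"]]))
  expect_false(is.na(fit$beta[["pos"]]))
})
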