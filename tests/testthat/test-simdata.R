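test_that("the generator is a pure function of its configuration", {
  s1 <- simulate_carriers(n_families = 100, family_size = 2, maf = 0.25,
                          hr = c(1.3, 1.0), seed = 13)
  s2 <- simulate_carriers(n_families = 100, family_size = 2, maf = 0.25,
                          hr = c(1.3, 1.0), seed = 13)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  s3 <- simulate_carriers(n_families = 100, family_size = 2, maf = 0.25,
                          hr = c(1.3, 1.0), seed = 14)
  expect_false(identical(s1$phenotypes, s3$phenotypes))
  expect_error(simulate_carriers(n_families = 10), "seed")

  # fixture files are byte-identical under the same seed
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- make_fixture_suite(d1, seed = 17)
  f2 <- make_fixture_suite(d2, seed = 17)
  for (nm in names(f1))
    for (part in names(f1[[nm]]))
      expect_identical(readLines(f1[[nm]][[part]]),
                       readLines(f2[[nm]][[part]]))
})

test_that("founder draws hit the configured allele frequency", {
  sim <- simulate_carriers(n_families = 10000, family_size = 1, maf = 0.3,
                           hr = 1.0, seed = 23)
  g <- sim$genotypes$dosages["causal", ]
  eaf <- mean(g) / 2
  se <- sqrt(0.3 * 0.7 / (2 * length(g)))
  expect_lt(abs(eaf - 0.3), 3 * se)
})

test_that("sibling genotypes are Mendelian-consistent with their founders", {
  sim <- simulate_carriers(n_families = 300, family_size = 3, maf = 0.3,
                           hr = 1.0, n_null_snps = 4, seed = 29)
  fam <- sim$truth$family
  allowed <- function(f1, f2) {
    tr <- function(fo) if (fo == 0) 0L else if (fo == 2) 1L else 0:1
    unique(outer(tr(f1), tr(f2), "+"))
  }
  for (fi in unique(fam)) {
    kids <- which(fam == fi)
    ok <- allowed(sim$truth$founders[1, fi], sim$truth$founders[2, fi])
    expect_true(all(sim$genotypes$dosages["causal", kids] %in% ok))
    for (j in 1:4) {
      okj <- allowed(sim$truth$null_founders[1, fi, j],
                     sim$truth$null_founders[2, fi, j])
      expect_true(all(sim$genotypes$dosages[1 + j, kids] %in% okj))
    }
  }
  # siblings correlate, as the clustered variance assumes
  g <- sim$genotypes$dosages["causal", ]
  sib_pairs <- do.call(rbind, lapply(unique(fam), function(fi)
    t(combn(which(fam == fi), 2))))
  expect_gt(cor(g[sib_pairs[, 1]], g[sib_pairs[, 2]]), 0.3)
})

test_that("under the null the empirical incidence reproduces mu(t)", {
  sim <- simulate_carriers(n_families = 20000, family_size = 1, maf = 0.3,
                           hr = 1.0, seed = 37)
  sv <- derive_survival(sim$phenotypes)
  mu <- default_incidence("BRCA1")
  # expected events = sum over ages of (carriers at risk) x per-year mass
  ages <- 18:80
  at_risk <- sapply(ages, function(a) sum(sv$t >= a))
  events <- sapply(ages, function(a) sum(sv$t == a & sv$d == 1L))
  expected <- at_risk * (1 - exp(-mu$rate))
  z <- (sum(events) - sum(expected)) / sqrt(sum(expected))
  expect_lt(abs(z), 3.5)
  # and age-locally: no systematic drift across the grid halves
  half <- ages < 50
  z1 <- (sum(events[half]) - sum(expected[half])) / sqrt(sum(expected[half]))
  z2 <- (sum(events[!half]) - sum(expected[!half])) /
    sqrt(sum(expected[!half]))
  expect_lt(abs(z1), 3.5)
  expect_lt(abs(z2), 3.5)
})

test_that("proband ascertainment keeps only families with an affected proband", {
  sim <- simulate_carriers(n_families = 200, family_size = 3, maf = 0.3,
                           hr = 1.2, ascertainment = "proband", seed = 41)
  ph <- sim$phenotypes
  probands <- ph[grepl("_I1$", ph$carrier_id), ]
  expect_equal(nrow(probands), 200)
  expect_true(all(!is.na(probands$age_bc)))
  # affected fraction is enriched relative to population sampling
  pop <- simulate_carriers(n_families = 200, family_size = 3, maf = 0.3,
                           hr = 1.2, seed = 41)
  expect_gt(mean(!is.na(ph$age_bc)), mean(!is.na(pop$phenotypes$age_bc)))
})

test_that("masking rates are honored, including the MNAR stress mode", {
  sim <- simulate_carriers(n_families = 3000, family_size = 1, maf = 0.3,
                           hr = c(1.0, 1.0), missing_label = 0.4,
                           missing_geno = 0.1, seed = 43)
  ph <- sim$phenotypes
  aff <- !is.na(ph$age_bc)
  miss_rate <- mean(is.na(ph$subtype[aff]))
  expect_lt(abs(miss_rate - 0.4), 3 * sqrt(0.4 * 0.6 / sum(aff)))
  geno_miss <- mean(is.na(sim$genotypes$dosages))
  expect_lt(abs(geno_miss - 0.1),
            3 * sqrt(0.1 * 0.9 / length(sim$genotypes$dosages)))

  mnar <- simulate_carriers(n_families = 3000, family_size = 1, maf = 0.3,
                            hr = c(1.0, 1.0), missing_label = 0.2,
                            mnar_shift = 0.4, seed = 47)
  aff2 <- !is.na(mnar$phenotypes$age_bc)
  s_true <- mnar$truth$subtype
  m1 <- mean(is.na(mnar$phenotypes$subtype[aff2 & s_true == 1]))
  m2 <- mean(is.na(mnar$phenotypes$subtype[aff2 & s_true == 2]))
  expect_lt(abs(m1 - 0.2), 0.06)
  expect_lt(abs(m2 - 0.6), 0.06)
})

test_that("the generator's disease process matches the estimator's model", {
  # labels observed at the true subtype shares
  sim <- simulate_carriers(n_families = 4000, family_size = 1, maf = 0.3,
                           hr = c(1.0, 1.0), f = c(0.25, 0.75),
                           missing_label = 0, seed = 53)
  sv <- derive_survival(sim$phenotypes, classification = "subtype")
  share_pos <- mean(sv$s[sv$d == 1L] == "positive")
  n_ev <- sum(sv$d)
  expect_lt(abs(share_pos - 0.25), 3 * sqrt(0.25 * 0.75 / n_ev))
})
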