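# carriermod

Association analysis of SNP genotypes with breast cancer risk — overall
and by tumor subtype — in *BRCA1* and *BRCA2* mutation carriers.

## The problem and the model

Carrier cohorts are assembled largely through cancer genetics clinics, so
affected women are heavily over-represented relative to a prospective
cohort. Estimating a genetic modifier's hazard ratio with a standard
survival analysis on such a sample is biased. `carriermod` implements the
retrospective-likelihood approach used in genetic-modifier studies: the
likelihood of each carrier is the probability of her **genotype**
(and, in the subtype model, her tumor-subtype label) **conditional on her
disease phenotype**, which removes the dependence on the
outcome-dependent sampling scheme.

The hazard model is a per-allele (log-additive) Cox form on a yearly age
grid,

    lambda(t | z) = lambda0(t) exp(beta * z),      z = 0, 1, 2 effect alleles,

with the extension to S competing tumor subtypes

    lambda_s(t | z) = lambda0_s(t) exp(beta_s * z),  s = 1..S.

The baselines are not free parameters: at every age they are calibrated
so that the genotype-averaged incidence among women still at risk equals
an external age-specific carrier incidence curve mu(t), and (for
subtypes) so that the genotype-averaged subtype shares among incident
cases equal the subtype mixture f_s. Affected carriers with missing
pathology enter with the label marginalized (missing at random).
Estimation is by maximum likelihood jointly over the log hazard ratios
and the allele frequency of the Hardy–Weinberg genotype prior, with a
family-clustered sandwich (robust) covariance for the non-independence
of relatives, a 1-df score test of beta = 0, and a Wald heterogeneity
test of equal subtype effects.

Around the core model the package provides variant QC (call rate, exact
Hardy–Weinberg test, MAF), genomic-control diagnostics (lambda and
lambda1000, QQ coordinates), Shrout–Fleiss one-way random-effects
intraclass correlation for comparing per-variant log hazard ratios
across cohorts, and a family-structured synthetic cohort generator that
shares the estimator's calibration, so every stage is testable without
consortium data.

## Worked example

Simulate a clinic-style cohort of 4,000 carriers in 2,000 sibships with
an ER-positive-specific variant (true HR 1.4 for ER-positive disease,
1.0 for ER-negative; MAF 0.3; 40% of tumors unlabeled), then fit the
competing-risk model:

```r
library(carriermod)
sim <- simulate_carriers(n_families = 2000, family_size = 2, maf = 0.3,
                         hr = c(1.4, 1.0), classification = "ER", seed = 7)
sv  <- derive_survival(sim$phenotypes, classification = "ER")
fit <- carrier_fit(sv, sim$genotypes$dosages["causal", ])
fit
#> Retrospective-likelihood carrier hazard model
#>   n = 4000 carriers (2000 families), 0 dropped for missing dosage
#>   events: negative 855, positive 263, unlabeled 692
#>             HR    lo    hi
#> negative 1.078 0.988 1.177
#> positive 1.565 1.322 1.854
#>   q-hat = 0.3016 (joint MLE), logLik = -4329.85
#>   heterogeneity: chi2(1) = 12.660, P_het = 0.000373
```

The per-subtype rows give the per-allele hazard ratio with its robust
95% CI: the planted ER-positive effect is recovered (1.57, CI
1.32–1.85) while the ER-negative arm stays near 1, and the
heterogeneity test flags the difference (P_het = 4 x 10^-4). `summary()`,
`coef()`, `vcov()`, `confint()`, `predict()` (genotype posteriors),
`residuals()`, `simulate()` and `plot()` methods are available on the
fitted object; `carrier_scan()` runs QC plus these fits across a whole
genotype matrix.

Cross-cohort agreement uses the packaged transcription of published
hazard ratios for the 74 breast-cancer susceptibility loci in carriers:

```r
eff <- susceptibility_loci()
icc_oneway(subset(eff, arm == "BRCA1.erpos")$log_effect,
           subset(eff, arm == "BRCA2.erpos")$log_effect)
#> one-way random-effects ICC = 0.65 (95% CI: 0.50 to 0.77), n = 73 pairs
#>   (1 incomplete pairs dropped)
```

i.e. the ER-positive associations in *BRCA1* and *BRCA2* carriers agree
strongly, on the natural-log hazard-ratio scale.

## Layout

- `R/` — model fitting (`carrier_fit`, `score_test`,
  `heterogeneity_test`, `robust_covariance`), calibration
  (`calibrate_baseline`), IO (`read_phenotypes`, `read_genotypes`,
  `derive_survival`), QC (`variant_qc`, `genomic_inflation`), agreement
  (`icc_oneway`, `icc_grid`), simulation (`simulate_carriers`,
  `make_fixture_suite`), pipeline (`carrier_scan`).
- `inst/extdata/susceptibility_loci_hr.csv` — the transcribed published
  hazard-ratio table behind `susceptibility_loci()`.
- `vignettes/retrospective-carrier-models.Rmd` — the methods vignette.
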