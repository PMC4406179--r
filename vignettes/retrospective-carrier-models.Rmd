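---
title: "Retrospective-likelihood models for genetic modifiers in mutation carriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrospective-likelihood models for genetic modifiers in mutation carriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carriermod)
```

## Why a retrospective likelihood

Cohorts of *BRCA1*/*BRCA2* mutation carriers are recruited mostly through
cancer genetics clinics, so women affected with breast cancer are far
over-represented relative to their population frequency. A prospective
survival likelihood $P(\text{phenotype} \mid \text{genotype})$ evaluated
on such a sample confounds the genotype's effect with the sampling
mechanism. The estimator in this package instead conditions the other
way around: each carrier contributes

$$P(\text{genotype}\; [\text{and tumor subtype}] \mid \text{disease phenotype}),$$

which is invariant to any ascertainment scheme that selects on
phenotypes. `prospective_fit()` implements the uncorrected comparator
purely so that simulations can exhibit the bias the conditioning
removes; the validation suite runs exactly that comparison under
proband-based sampling.

## The model

Phenotypes are reduced to $(t_i, d_i, s_i)$ by the censoring rule: each
woman is followed from age 18 and censored at the first of breast cancer
diagnosis, ovarian cancer diagnosis, bilateral prophylactic mastectomy,
or last follow-up (`derive_survival()`). $d_i$ indicates breast cancer,
$t_i$ is the integer age at event or censoring, and $s_i$ is the tumor
subtype label of an affected carrier, possibly missing. Given the
effect-allele count $z \in \{0,1,2\}$, the yearly hazard of a
first breast cancer of subtype $s$ is

$$\lambda_s(t \mid z) = \lambda_{0s}(t)\, e^{\beta_s z},$$

a per-allele (multiplicative) model; the single-outcome model is the
case $S = 1$. Time is discrete in whole years: the survivor function is
a product of $e^{-\lambda}$ factors and the probability of an event in
the year of age $t$ is $1 - e^{-\lambda(t|z)}$, which matches the yearly
resolution of the incidence inputs and makes the baseline calibration
closed-form. When breast cancer ties with another censoring event at the
same integer age, the event is counted (ties are not resolvable at
yearly resolution; counting the event is the conservative choice for the
power properties we test).

### Baseline calibration

The baselines $\lambda_{0s}(t)$ are pinned, not estimated: carrier
incidence curves $\mu(t)$ are an external input (`read_incidence()`;
`default_incidence()` ships smooth illustrative curves per gene for
simulation work). At each age, with HWE genotype prior $p_g$ at allele
frequency $q$ and survivor functions $S(t\mid g)$ accumulated from
earlier ages,

$$\lambda_{0s}(t) = f_s(t)\,\mu(t)\,
  \frac{\sum_g p_g S(t\mid g)}{\sum_g p_g S(t\mid g) e^{\beta_s z_g}},$$

so that the genotype-averaged total incidence among survivors equals
$\mu(t)$ and the genotype-averaged share of subtype $s$ among incident
cases equals the mixture $f_s(t)$, both to numerical accuracy (the
constraint residual is checked to be below $10^{-10}$ at every age, for
any $\beta$ in the range the tests sweep). The recursion runs over ages
18–80; events beyond 80 are censored at 80.

### The likelihood

For carrier $i$ with genotype $g_i$,

- unaffected, censored at $t$: $L(t,0 \mid g) = \exp\{-\sum_{u \le t} \lambda(u\mid g)\}$,
- affected at $t$, label $s$: $L = S(t\mid g)\,(1-e^{-\lambda(t\mid g)})\,\lambda_s(t\mid g)/\lambda(t\mid g)$,
- affected at $t$, label missing: the label-marginalized version (missing at random).

The contribution is the joint conditional
$P(g_i, s_i \mid t_i, d_i) = p_{g_i} L(t_i,d_i,s_i \mid g_i) /
\sum_{g'} p_{g'} L(t_i,d_i \mid g')$: the subtype label is part of the
outcome, so the normalizer marginalizes it. Two consequences are used as
exact test identities: at $\beta = 0$ the genotype posterior equals the
HWE prior (the likelihood is phenotype-free), and when all $\beta_s$ are
equal the subtype log-likelihood equals the single-outcome one plus
$\sum \log f_{s_i}$ over labeled events. Competing censoring events and
the follow-up age distribution are genotype-independent, so their
probabilities cancel from the conditional and need not be modeled.

### Estimation, testing, variance

`carrier_fit()` maximizes the cohort log-likelihood over
$(\beta_1,\dots,\beta_S, q)$ with the baselines recalibrated at every
trial value (a profile construction). Estimating $q$ inside the
retrospective likelihood avoids plugging in the ascertainment-biased
sample allele frequency; `q = "plugin"` is available for speed across
many SNPs, and is the default in `carrier_scan()`. The subtype mixture
$f$ defaults to the label shares among labeled cases, constant in age
(an age-varying matrix can be supplied); $f$ is held fixed during
optimization, since under the missing-at-random assumption the labeled
shares estimate it consistently and the hazard-ratio profile is flat in
small $f$ perturbations.

Quasi-Newton (BFGS) optimization uses a logit transform for $q$; after
convergence the central-difference gradient (step $10^{-5}$) must have
infinity-norm below $10^{-2}$ — on the scale of a log-likelihood over
thousands of carriers this bounds the parameter offset by far less than
one standard error, while remaining achievable given the cancellation
noise of finite differences. Non-convergence raises an error carrying
the last iterate and gradient norm. If every event carries the same
genotype the fit is flagged as separated and no estimate is returned.

Model-based covariance is the inverse observed information (numerical
Hessian). The reported intervals use the family-clustered sandwich
$A^{-1} B A^{-1}$ with $B$ built from score contributions summed within
families (`robust_covariance()`), accommodating relatedness without an
explicit kinship model. `score_test()` evaluates the per-carrier score
at $\beta = 0$ (central differences through the recalibration) with the
clustered variance; `heterogeneity_test()` is the Wald test of the
$S-1$ contrasts $\beta_s - \beta_S$.

### Stratification

Analyses of multinational cohorts stratify by country. In this
implementation strata enter through the incidence input: passing a named
list of curves calibrates each stratum against its own curve, and
`pool_strata()` merges strata below a minimum size (default 50) either
through an explicit map of geographically close groups or into a single
pooled remainder. A single allele frequency is estimated across strata:
with a shared incidence curve, per-stratum baselines are identical, and
per-stratum allele frequencies would add parameters that matter only
under frequency heterogeneity the synthetic cohorts do not generate.
Calendar-year dependence of incidence is likewise reduced to one
age-indexed curve per gene; both reductions are deliberate
simplifications of this implementation.

## Quality control and scan diagnostics

`variant_qc()` applies, in order: call rate $\ge 0.95$, non-monomorphic,
exact Hardy–Weinberg $p \ge 10^{-7}$, and — for association analyses —
minor allele frequency $\ge 0.03$, recording the first failing rule per
variant. The HWE test is the exact conditional test (the $\chi^2$
approximation is unusable at $10^{-7}$ tails). MAF is computed over all
genotyped carriers per gene. `genomic_inflation()` computes
$\lambda$ as the median association $\chi^2$ over 0.4549 and rescales it
to a 1,000-case/1,000-control study as
$\lambda_{1000} = 1 + (\lambda-1)(1/n_\text{cases}+1/n_\text{controls})/(2/1000)$
— the standard sample-size adjustment, since the scan-level diagnostic
is otherwise not comparable across cohort sizes. `qq_points()` uses the
$-\log_{10}(\text{rank}/(n+1))$ expected quantiles with an optional
exclusion list for variants placed on an array because of known
associations. Significance conventions are carried as configuration:
0.05 for known susceptibility loci, $5\times10^{-8}$ array-wide, with a
$10^{-6}$ reporting tier.

## Cross-cohort agreement (ICC)

`icc_oneway()` implements the Shrout–Fleiss single-measurement ICC under
the one-way random-effects model: each SNP is a target measured by two
analyses, $\mathrm{ICC} = (MS_B - MS_W)/(MS_B + MS_W)$ for $k=2$, with
the F-based confidence interval on $(n-1, n)$ degrees of freedom.
Agreement is computed on **signed** natural-log hazard ratios, oriented
to each SNP's effect allele: near-zero cross-subtype cells would be
impossible under agreement of absolute values, which pins down this
reading; `magnitude = TRUE` provides the alternative ($|\log HR|$)
for comparison. SNPs missing an estimate in either arm are dropped
listwise per cell, and the standard error of a published estimate is
recovered from its 95% CI as $(\ln hi - \ln lo)/(2 \times 1.959964)$.
The packaged `susceptibility_loci()` table transcribes the published
per-SNP hazard ratios for the 74 susceptibility loci in carriers
(overall, ER-negative, ER-positive, per gene); `scripts/acceptance.R`
recomputes the four BRCA1-vs-BRCA2 agreement cells from it.

## The synthetic cohort generator

`simulate_carriers()` draws sibships from two unobserved founders with
HWE founder genotypes and Mendelian transmission — enough family
structure to induce the within-family genotype correlation the clustered
variance must absorb, without full multi-generation pedigrees. The
disease process uses the same calibrated discrete-time hazards as the
estimator, so the generator and the fitting engine share one model and
parameter recovery is a sharp test. Defaults emulate the study
conditions the analysis assumes: 40% of tumor labels missing at random
(matching the roughly 60% pathology coverage of carrier cohorts), an
ER-positive-like subtype share of 0.25 for two subtypes, competing
ovarian-cancer (0.004/yr from age 40) and mastectomy (0.002/yr from 25)
censoring, follow-up ages centered at 55 (SD 12), and either population
sampling or clinic-style ascertainment in which the first family member
is a proband who must be affected. A deliberately MNAR stress mode
(`mnar_shift`) masks one subtype preferentially to probe the
missing-at-random assumption.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, country/calendar heterogeneity in incidence, pathology
misclassification, genotyping batch effects, or informative censoring.
Passing tests therefore demonstrate internal correctness of the
estimator under its own assumptions — not robustness to every way real
consortium data violate them.

## Validation design and problem sizes

The suite checks, at desk scale: exact closed forms (calibration at
$\beta=0$, first-age formulas, HWE priors), equivalence to independent
scalar-loop enumeration oracles at $10^{-12}$ on ten-carrier toys,
parameter recovery (100 replicates of 5,000 carriers at HR 1.2 and MAF
0.3, with robust-CI coverage), type-I error of the score and
heterogeneity tests (1,000 replicates at 500–800 carriers), the
proband-ascertainment bias contrast over 100 replicates, exact behavior
of the QC filters on planted failures, and genomic-control calibration
of 10,000 null SNPs on one 8,000-carrier cohort. These sizes were chosen
so each property has enough Monte-Carlo precision to be meaningful while
the whole suite stays convenient to run routinely.

## Known limitations

- Under family-based ascertainment the per-carrier conditioning is exact
  for probands but approximate for their relatives, whose genotype prior
  is enriched by the proband's status; the joint allele-frequency
  estimate absorbs most of this, and the residual effect is a small
  attenuation — far smaller than the upward bias of the uncorrected
  prospective fit, which is the contrast the validation suite tests.
  A full pedigree likelihood with kinship is out of scope.
- Competing non-breast-cancer mortality is not modeled (censoring only).
- Subtype labels are consumed as given; harmonization of staining
  cutoffs across studies is upstream of this package.
- The one-year discretization makes within-year timing unidentifiable;
  incidence inputs must be yearly.
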