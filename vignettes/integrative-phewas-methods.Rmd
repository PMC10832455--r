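---
title: "Methods: triangulated PheWAS, Mendelian randomization, and canalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triangulated PheWAS, Mendelian randomization, and canalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phetriad)
```

# The analysis in brief

`phetriad` implements an integrative phenome-wide association (PheWAS)
strategy for circulating metabolites — the motivating application is
polyunsaturated fatty acids measured in a population biobank — against a
large panel of binary disease endpoints (phecodes). Evidence is layered:

1. **Direct (non-genetic) association.** For each metabolite and disease,
   logistic regression of disease status on the metabolite Z-score with
   covariates age, sex, age², and ten genotype principal components.
2. **Genetic association.** The same model with the standardized metabolite
   polygenic score (PGS-m) in place of the measured level. Because a PGS
   captures only part of the metabolite variance, these effects are
   attenuated relative to the direct ones (see *Attenuation* below).
3. **Triangulation.** A metabolite–disease link is called *suggestive* when
   both tests pass a scan-wide Bonferroni threshold and agree in direction
   (OR > 1 risk, OR < 1 protective). Disease-group enrichment among the
   suggestive associations is quantified by a relative risk with a
   two-sided Fisher exact test.
4. **Mendelian randomization (MR).** Two-sample MR from exposure and
   outcome GWAS summary statistics: IVW as the primary estimator, weighted
   median as robustness check, Egger as pleiotropy diagnostic, preceded by
   Cochran's-Q outlier pruning. Because the triangulated associations under
   study are protective, MR support additionally requires OR < 1.
5. **Interaction and canalization.** Metabolite-by-body-weight interaction
   models (continuous Z-scores or obesity status for BMI and WHR), and the
   delta-departure statistic contrasting observed versus expected
   deviations between the tails of score-percentile disease-prevalence
   curves in obese versus non-obese (or low- versus high-metabolite)
   strata.

Every stage runs on synthetic cohorts from `generate_cohort()` /
`generate_summary_stats()`, so the full pipeline is testable without
access-restricted individual-level data.

# Preparation of measurements

Repeated metabolite measurements carrying a QC warning are removed first;
the median of the surviving repeats is the individual's level, missing if
none survive (`collapse_measurements()`). Z-scores use the sample SD
(n−1 denominator); the underlying method description does not fix the
denominator and the difference is negligible at cohort scale, so the
conventional, stable choice is used. Body-weight medians feed
WHR = waist/hip; obesity cutoffs are strict inequalities — BMI > 30,
WHR > 0.85 (women) / > 0.95 (men) — so a boundary value is non-obese,
matching the "≤ cutoff" definition of the non-obese groups. Diseases with
fewer than 50 cases are excluded ("at least 50" is inclusive:
`min_case_filter()` keeps a disease with exactly 50). Missing covariates
exclude an individual from the affected model only (complete-case per
model), not from the whole analysis.

Allele-sum scoring (`score_individuals()`) multiplies effect-allele dosages
by weights and sums; chromosome-chunked scoring is exactly additive. A
weight whose effect allele matches the dosage allele or its strand
complement is used as-is; one matching the other allele (or its complement)
has its sign flipped; anything unresolvable is dropped with a warning. The
constant offset that distinguishes a sign flip from a full 2−dosage
conversion is immaterial because downstream models standardize the scores.

# Association models and attenuation

`fit_logistic()` wraps the IRLS maximum-likelihood fit with explicit
preconditions (both classes present, full-rank design, convergence within
1e-8) and flags possible complete separation when any fitted probability is
within 1e-8 of 0 or 1 — relevant for diseases near the 50-case floor. Age
is centered before squaring; this only reparametrizes the covariate space
and stabilizes the numerics. Confidence intervals are Wald on the log-OR
scale, `exp(beta ± 1.96·se)`.

With the generative model `level = sqrt(h2)·PGS + sqrt(1−h2)·noise`, the
regression of disease on the standardized PGS recovers approximately
`sqrt(h2)` times the per-SD level effect, because `cov(level, PGS) =
sqrt(h2)`. At the default `h2_pgs = 0.5` the PGS-mode effect is therefore
attenuated by ≈ 0.71 — the mechanism by which the genetic scan yields fewer
significant associations than the direct scan. The test suite checks this
at n = 100,000, where the Monte-Carlo error is small relative to 2 SE.

# Triangulation and enrichment

The scan-wide threshold is `alpha / (n_diseases × n_metabolites × 2)`; with
1,254 diseases and 3 metabolites this is 6.65 × 10⁻⁶. Direction concordance
uses the sign of the log-OR, not CI overlap. Group enrichment is

\[ RR = \frac{N_{sig,group}/N_{sig}}{N_{group}/N_{total}} \]

with a two-sided Fisher exact test on the 2×2 count table
(significant/not × in-group/not); the count table is the only object on
which an exact test is defined, so proportions are never tabulated. The
group-level threshold divides alpha by the number of groups containing at
least one significant disease — data-dependent by default (15 in the
motivating analysis), overridable via `n_groups`.

# Mendelian randomization

Instruments are exposure SNPs with p < 5e-8. Harmonization aligns outcome
effects to the exposure's effect allele, flipping signs for swapped
alleles, accepting strand complements, and dropping palindromic SNPs with
allele frequency in [0.42, 0.58].

IVW is fixed-effect — the `se_y⁻²`-weighted least-squares slope through the
origin — with Cochran's Q reported; outliers are removed beforehand by
iteratively dropping the largest per-SNP Q contribution while it exceeds
the chi-square(1) quantile at a per-round Bonferroni level
(0.05/n instruments, configurable), never going below 3 instruments. A
multiplicative random-effects variant was considered and not adopted:
with explicit outlier pruning first, the fixed-effect SE is the cleaner
primary, and the choice is documented and configurable rather than silent.
The weighted median interpolates the ratio estimate at cumulative weight
0.5 with weights `(beta_x/se_y)²`; its SE comes from a seeded parametric
bootstrap (default 1000 draws), so results are deterministic under a fixed
seed. Egger is the `se_y⁻²`-weighted regression with intercept after
orienting all exposure effects non-negative, with the usual residual-
variance (multiplicative overdispersion) SEs. The method registry exposes
IVW, weighted median, and Egger; IVW and the weighted median drive the
support flags (`mr_supported`: IVW p < 0.05 and OR < 1; `dual_support`:
weighted median also p < 0.05).

# Canalization: delta observed, expected, departure

For a chosen disease the cohort is split into two strata — obese versus
non-obese under one body-weight measure, or low versus high metabolite
(dichotomized at the mean, boundary inclusive on the high side). Within
each stratum, individuals are ranked by the polygenic score and divided
into 100 near-equal bins (stable ties; bin sizes differ by at most one);
per-bin prevalence is the case fraction. The 2% tails are the top and
bottom 2 bins of 100, pooled case-weighted; the *tail difference* is top
minus bottom, and *delta observed* is the tail difference of stratum a
minus that of stratum b (signed; its absolute value enters the departure).

*Delta expected* simulates the same quantity under a smooth expectation:
per stratum, a logistic regression of case counts on the percentile index
gives fitted per-bin prevalences; each iteration redraws bin case counts as
Binomial(n_b, fitted_b) — the binomial draw is what "equal variance given
bin size" amounts to — rebuilds the curves, and records the simulated
delta. A linear-in-percentile alternative (`model = "linear"`) is provided
because the smooth model is a modelling choice, not forced by the method's
description. The default is 10 iterations to mirror the source analysis;
for a stable SD we recommend ≥ 1000, and both are exposed.

The departure is

\[ \frac{\mathrm{mean}(|\Delta_{exp}|) - |\Delta_{obs}|}{\mathrm{sd}(|\Delta_{exp}|)} , \]

positive when the strata deviate less than expected (canalization),
negative when more (decanalization). Whether delta observed should be
signed or absolute before comparison is ambiguous in the method's
description; the implementation computes the signed value and takes
absolute values only inside the departure, and both are reported. Taking
2% tails over bins rather than individuals is equivalent up to rounding
and keeps the statistic invariant under monotone score transforms.

Why does a planted PGS-by-obesity interaction drive the departure negative?
The expected curves are linear in the *percentile* index on the logit
scale, whereas a liability linear in the *score* is steeper at the
percentile tails; the excess tail deviation beyond the smooth fit grows
with the slope, so a stratum whose gradient is steepened by the
interaction contributes more unexplained tail deviation than its
counterpart, and |delta observed| exceeds the simulated expectation. With
no interaction the excess cancels between strata and the departure is
centered at zero — both behaviours are verified in the test suite (30
seeds per arm, n = 40,000 per cohort, gamma = −0.4 for the planted arm).

# The synthetic cohort generator

The generator is the study's stand-in for restricted biobank data and is
first-class, tested code. Its defaults describe the emulated conditions:

* **Demographics.** Age uniform on 40–70 years, 54% female, 10 standard
  normal genotype PCs.
* **Body measures.** log-BMI normal with median 27 and SD calibrated so
  that P(BMI > 30) equals the configured 25%; WHR normal per sex with SD
  0.065 and means calibrated to the configured 45% (women) / 30% (men)
  above the standard cutoffs — reproducing the observation that
  substantially more women are WHR-obese than BMI-obese. BMI and WHR share
  a Gaussian copula with correlation 0.5. Only ranks and cutoffs matter
  downstream, so marginal realism beyond this is not attempted.
* **Metabolites.** PGS-m ~ N(0,1); latent level `sqrt(h2)·PGS +
  sqrt(1−h2)·noise` with `h2_pgs = 0.5` by default — the share of
  metabolite variance a well-powered score explains; mapped to a positive
  concentration scale (mean 5, SD 1) and observed as repeats with
  measurement SD 0.1 plus QC warnings at the configured rate. Repeats
  share the individual's true level, which makes the median collapse
  testable.
* **Diseases.** Status is drawn from a logistic model directly on the
  log-odds scale (not a probit liability threshold) so that the analysis
  estimand equals the generative coefficient and parameter-recovery tests
  are exact. `prs_r2_liability` converts to a PRS coefficient via the
  logistic-liability variance π²/3 when no explicit `beta_prs` is given.
  Interactions are planted as a product of the chosen predictor (latent
  level or PGS) with the chosen body-weight variable (Z or obesity
  status), matching the analysis models term for term.
* **Summary statistics.** True exposure effects uniform on [0.05, 0.15],
  oriented to the exposure-raising allele (the usual instrument-table
  convention — this is what makes "directional" pleiotropy directional);
  `se = 1/sqrt(2·maf·(1−maf)·n)`, the standard GWAS approximation, so
  instrument strength is controlled by the sample size; invalid
  instruments add a direct outcome effect `N(pleiotropy_mean,
  pleiotropy_sd)`.

What the generator does **not** emulate: linkage disequilibrium between
instruments, population structure, age-dependent incidence, comorbidity
between diseases, and correlation between metabolites. Passing tests
therefore demonstrate the statistical machinery is correct under the
stated model, not that real-data confounding is absent.

# Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to keep Monte-Carlo error
well inside the asserted tolerances: 100 replicates for MR recovery
(n_snps = 50, outcome GWAS n = 500,000 in the invalid-instrument scenario,
where the weighted median's robustness bound is the claim under test);
200 replicate cohorts of n = 2,500 for type-I calibration; n = 100,000 for
single-shot effect recovery; 30 seeds × n = 40,000 for the canalization
calibration; and a 20,000-individual, 12-disease, 3-metabolite demo for the
end-to-end run. Seeds flow from one root through named streams
(`derive_seed()`), so stages are individually reproducible.

Degenerate inputs are explicit errors, not NaNs: single-class outcomes,
rank-deficient designs, zero-variance Z-scores, all-case/all-control
canalization strata, zero SD of expected deltas, fewer individuals than
bins. P-values are clamped away from exactly zero so they remain in (0, 1].

# Limitations

The delta-expected model is a documented reading of a sparsely specified
procedure; with only 10 iterations its SD is noisy, and departure values
should be interpreted on the recommended ≥ 1000 iterations when precision
matters. The outlier-removal rule is a standard Q-contribution procedure
standing in for an unpublished variant. Enrichment assumes the group map
partitions the disease universe. None of the synthetic defaults should be
mistaken for estimates from real data.
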