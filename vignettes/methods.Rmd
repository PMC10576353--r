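---
title: "Models, conventions, and calibration in epimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions, and calibration in epimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimr)
```

This vignette documents the statistical models behind `epimr`, the
conventions chosen where the methodology literature admits more than
one, and what the simulation-based tests do and do not establish.

## The study design

The package supports a two-arm investigation of a circulating
biomarker and a binary disease outcome:

1. a **biomarker arm**: the biomarker measured at baseline in a nested
   case-control sample of a prospective cohort, with 1:1
   incidence-density matching, analyzed by conditional logistic
   regression; and
2. a **genetic arm**: two-sample Mendelian randomization (MR) using
   GWAS summary statistics for the biomarker (instrument panel) and
   for the disease, with colocalization as a complementary check, and
   a mediation analysis quantifying how much of an adiposity-disease
   association runs through the biomarker.

## Summary-statistic MR

All estimators consume an `instrument_set`: allele-aligned pairs
(β_X, SE_X, β_Y, SE_Y) per variant, with β_X in biomarker-SD units and
β_Y on the log-odds scale. `harmonize()` aligns the outcome records to
the exposure's effect allele, attempting strand complementation before
dropping a variant. Palindromic (A/T, G/C) variants cannot be resolved
by strand: by default they are dropped when the minor-allele frequency
exceeds 0.42 (the frequency signal is then too weak to orient the
alleles) and otherwise oriented by comparing allele frequencies across
the traits.

* **Wald ratio** (single instrument): β_Y/β_X with the first-order
  delta-method SE, SE_Y/|β_X|. The second-order term (adding
  β_Y²SE_X²/β_X⁴) is available but off by default; for strong
  instruments it changes SEs by well under 10%.
* **Fixed-effects IVW**: weighted least squares of β_Y on β_X through
  the origin with weights 1/SE_Y², algebraically the precision-weighted
  mean of per-variant Wald ratios with weights (β_X/SE_Y)². No
  overdispersion scaling by default; a multiplicative random-effects
  flag exists.
* **Correlated-instrument IVW**: generalized least squares through the
  origin with Ω = D ρ D (D = diag(SE_Y), ρ the instrument correlation
  matrix), solved via the Cholesky factor. With ρ = I this reduces
  exactly to the fixed-effects IVW — a property tested to 1e−12.
  Correlation matrices are user-supplied (or simulated); the package
  deliberately does not estimate LD from reference panels.
* **MR-Egger**: weighted regression with a free intercept after
  orienting all instruments to β_X ≥ 0. The intercept is the
  directional-pleiotropy estimate.

**Egger standard-error conventions.** With k instruments the residual
degrees of freedom are k − 2; the default multiplies both SEs by
max(1, σ̂) (σ̂² the weighted residual mean square), and p-values use a
normal reference, with a t-reference (df = k − 2) available. With
k = 3 these choices matter: the truncation can only enlarge SEs, so
the intercept test is *conservative* under the null (its theoretical
size with k = 3 is about 0.038 at nominal 0.05), while the untruncated
"fixed" convention has nominal size. The calibration suite therefore
checks nominal 0.05 size against the fixed convention and verifies the
truncated default is no more liberal. Published pleiotropy p-values
rounded to two decimals cannot adjudicate between the conventions,
which is why both are exposed.

* **Heterogeneity between strata** (e.g. men vs women): Cochran's
  inverse-variance Q with a fixed-effect pooled mean, chi-square with
  (strata − 1) df. `log_or_from_ci()` reconstructs (β, SE) from
  published ORs with 95% CIs (CI width / 3.92 on the log scale).

**Rounding propagation.** Published instrument coefficients are
typically printed at two decimals. Estimates recomputed from printed
inputs therefore differ from estimates computed on the unrounded data.
The test suite treats published point estimates as *band* targets: it
varies every printed β and SE over its half-ulp range (±0.005) and
checks the published value falls inside the attainable interval, while
the package's own point estimates on the printed inputs are checked
against closed-form oracles at 1e−10.

## Instrument strength and power

Per-variant variance explained uses β²/(β² + n·SE²) by default. The
alternative 2p(1−p)β² (valid for SD-unit effects) is exposed; for the
packaged panel the se-based total (0.96%) is the one consistent with
the published "about 1%" and F ≈ 65, while the frequency-based total
(1.36%) is not, which is why se-based is the default. The F-statistic
is the multiplicative form ((n−k−1)/k)·(R²/(1−R²)); the alternative
literal reading of the printed formula with a division between the two
factors yields values near 7e5 and is inconsistent with any published
F, so it is not implemented. Power for a binary outcome follows the
standard normal approximation on the log-OR scale with variance
1/(Nφ(1−φ)R²); `minimal_detectable_or()` and `power_at_or()` are exact
inverses (tested to 1e−6).

## Enumeration colocalization

Per-variant evidence is the Wakefield approximate Bayes factor: with
V = SE², z = β/SE and shrinkage r = W/(W + V),
log ABF = ½log(1 − r) + z²r/2. Prior effect SDs √W default to 0.2
(SD units) for quantitative and 0.15 (log-odds) for binary traits —
the established convention; the analysis this package reimplements
stated only the colocalization priors, not W. Hypothesis weights are

* H0 = 1, H1 = p1·ΣB1, H2 = p2·ΣB2,
* H3 = p1·p2·(ΣB1·ΣB2 − ΣB1B2), H4 = p12·ΣB1B2,

normalized to posterior probabilities. All sums use log-sum-exp, so
z-scores of any magnitude are safe. Defaults p1 = p2 = 1e−4 with
p12 = 1e−5 ("standard") or 1e−4 ("relaxed"); the relaxed-vs-standard
contrast changes only p12, reading the published "prior probability"
as the prior of the colocalization hypothesis — the hypothesis the
prior is attached to in the enumeration framework. Raising p12 can
only raise PP4 (tested on every simulated dataset).

## Matched case-control modelling

`clogit_fit()` maximizes the exact conditional likelihood (delegated
to the survival package's Cox machinery with unit follow-up, the same
engine `survival::clogit` uses). For 1:1 sets this equals no-intercept
logistic regression on case-minus-control differences; the suite
verifies the identity on random data to 1e−6. Under incidence-density
sampling the exponentiated coefficients estimate incidence rate
ratios, which is why results print as RRs. Matching factors are
absorbed by the conditioning: adding a within-set-constant covariate
changes nothing (tested).

Conventions:

* **Quintiles**: cut-offs are the 20/40/60/80th percentiles of the
  *control* distribution per sex, linear-interpolation empirical
  quantiles (R type 7) by default and configurable, since published
  category ranges at one-decimal precision cannot identify the rule.
  Categories are half-open [low, high); with tied (degenerate)
  cut-offs, ties resolve to the lowest category. Trend tests enter the
  sex-specific quintile medians of controls as a continuous score.
* **Per-SD scaling** divides by the overall control SD.
* **Waist residuals**: OLS of waist on BMI and height over complete
  cases avoids collinearity in body-size-adjusted models; subjects
  missing waist receive the sex-specific median residual (flagged),
  with complete-case analysis as the sensitivity option.
* **Exclusions** (e.g. baseline diabetes, early follow-up cases)
  operate at the set level: excluding a case removes its whole set.
* **Fractional polynomials**: FP1 powers {−2, −1, −0.5, 0, 0.5, 1, 2,
  3} (0 = log), FP2 pairs with repeated powers contributing x^p and
  x^p·log x; non-linearity is the likelihood-ratio test of the best
  FP2 against the linear model on 3 df.
* **Spearman partial correlation**: rank, residualize ranks on the
  controls by OLS, Pearson-correlate the residuals, t-test on
  n − 2 − q df.

## Mediation under the nested design

`mediate_ncc()` uses the product method with no exposure-mediator
interaction: a linear mediator model fitted **among controls** (under
incidence-density sampling controls represent the risk-set population;
a whole-sample option exists but over-represents cases) and a
conditional-logistic outcome model on exposure + mediator +
adjustments. For an exposure increment δ, log NDE = β_exp·δ and
log NIE = α₁·β_med·δ under the rare-outcome approximation; the
proportion mediated is log NIE / log(total) on the log-OR scale.
Intervals come from a nonparametric bootstrap over matched sets
(resampled sets get fresh identifiers). The decomposition identity
log(total) = log NDE + log NIE holds exactly by construction.

## Synthetic data: what it emulates, and what it does not

The generators define the package's reference study conditions.

* `simulate_cohort()`: sex-specific log-normal biomarker with control
  medians 12.1 (men) and 18.3 ng/mL (women); log-scale SD 0.42 chosen
  once to match the reported control interquartile ranges (9.0–16.0
  and 14.0–24.5 ng/mL), which yields an overall control SD close to
  the 8.9 ng/mL scaling constant. Anthropometry (BMI ~ N(26.2, 3.5²),
  sex-specific height, waist regressed on both with SD 4.5 cm) and an
  age distribution centered at 58 (SD 7) reproduce the scale of the
  emulated cohort's control table; eight centers; 4.6% missing waist.
  Event times are exponential with log-rate linear in age (0.05/yr),
  waist (0.012/cm direct), and the biomarker (0.1 per 8.9 ng/mL), with
  baseline hazard 0.004/yr and 12-year censoring, giving ≈5%
  cumulative incidence — rare enough for the rare-outcome mediation
  approximation. The per-SD effect is defined against the fixed
  reference SD (8.9), not the realized sample SD, so recovery tests
  have an exactly known target. Defaults give a mediated proportion of
  waist-through-biomarker of roughly 8–10%.
* `incidence_density_match()`: risk sets at each case's event time
  within sex × center strata and a ±2-year age caliper (a tractable
  stand-in for center-specific matching protocols); controls may be
  reused and may later become cases; never uses future information.
* `simulate_gwas_summary()`: three instruments with the published
  allele frequencies and relative effect sizes, rescaled to a 1% total
  R²; exposure GWAS n = 20,436; outcome sample with the published
  case/control totals via a logistic model whose intercept sets the
  case fraction. Per-variant statistics come from OLS and logistic
  fits, so SEs carry genuine sampling noise.
* `simulate_ld_region()`: dosages as sums of two thresholded AR(1)
  latent Gaussian haplotypes; the latent correlation is
  sin(πρ/2) so the realized dosage lag-1 correlation matches the
  requested ρ_LD (exact at EAF 0.5).

Limitations worth keeping in mind: the cohort generator does not model
the full covariate battery of a real cohort (diet, additional
biomarkers), center-specific age protocols, or biomarker measurement
error; LD is stationary AR(1) rather than block-structured; genotypes
are Hardy-Weinberg independent draws. Passing recovery tests
establishes internal consistency of estimator + design under these
conditions, not robustness to features the generators omit.

## Problem sizes and numerical choices

Calibration runs use: 200 replicates of the full-scale two-sample MR
(exposure n = 20,000; 20,000 cases/20,000 controls; θ = 0.1) for IVW
bias and coverage; 2,000 reduced-scale replicates (5,000/5,000/5,000,
θ = 0) for Egger intercept size; 50 shared-causal and 50
distinct-causal regions (m = 50, ρ_LD = 0.8, n = 10,000) for
colocalization discrimination; and 100 replicates of 1,000 matched
sets drawn from 23,000-subject cohorts for end-to-end rate-ratio
recovery. Monte-Carlo acceptance bands are ±2 MC standard errors
around truth and [0.92, 0.98] for nominal-95% coverage.

Numerical conventions: all 95% intervals use z = 1.959964; GLS solves
use Cholesky factors; Bayes-factor sums use log-sum-exp; the
conditional-likelihood maximizer inherits the survival package's
Newton-Raphson with its convergence diagnostics surfaced via
`converged` (separation flagged, not silenced); p-values are two-sided
normal/chi-square/t tails computed at full precision. Degenerate
inputs (zero exposure effect in a Wald ratio, non-positive-definite
correlation, uninformative matched sets, zero-SD standardization) are
errors by contract rather than silent NAs.

## Known limitations

* No weighted-median/mode MR estimators, MR-PRESSO, or Steiger
  filtering; no multi-causal (SuSiE-style) colocalization or credible
  sets; no liftover between genome builds; no multiple-imputation
  machinery; no four-way mediation decomposition or multiple
  mediators.
* The published cohort RRs and region-specific colocalization
  posteriors of the emulated study depend on restricted
  individual-level and regional data; they are consistency surfaces
  for the simulators, not exact reproduction targets. The genome build
  of the packaged variant positions is recorded as printed, without
  asserting a build.
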