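---
title: "Methods: exposure-wide survival scanning and attributable-fraction estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure-wide survival scanning and attributable-fraction estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposcan)
```

## The analysis model

`exposcan` implements a hypothesis-free risk-factor analysis for an
incident disease — Parkinson's disease is the motivating outcome — in a
biobank-style cohort. The chain is: preprocess raw baseline variables;
scan every modifiable exposure with an adjusted Cox proportional-hazards
model under a Bonferroni threshold; compose the significant factors into
per-domain risk scores; examine joint and gene–environment effects;
decompose exposure–blood-assay associations through disease by mediation;
probe causality with two-sample Mendelian randomization; and translate
domain-level contrasts into population attributable fractions (PAFs).

Throughout, the hazard for participant $i$ is modelled as
$\lambda_i(t) = \lambda_0(t)\exp(x_i^\top\beta)$, fitted by maximizing the
Cox partial likelihood with the Efron correction for ties (the default of
the major survival implementations and the better approximation under
heavy ties). Convergence follows `survival::coxph` (up to 100 iterations).
Wald inference is used everywhere; confidence intervals are
$\exp(\hat\beta \pm 1.96\,\mathrm{se})$.

## The synthetic cohort generator

Real biobank phenotype data cannot be redistributed, so the package's
evidence comes from a generator that emulates the relevant structure:

* **Seven exposure domains** (socioeconomic status, medical history,
  psychosocial factors, physical measures, early life, local environment,
  lifestyle) with a configurable number of continuous, binary and
  three-level categorical variables per domain. Within a domain,
  variables share a latent Gaussian factor with equicorrelation `rho`
  (default 0.2) so that collinearity filtering and PCA communalities have
  signal to work with; the correlation of the real exposures is unknown,
  so this default is a free parameter, not an estimate.
* **Raw-export artifacts**: special negative codes (−1 "do not know",
  −3 "prefer not to answer", −10 "less than one" in count-coded
  variables), cell-level missingness, and multi-instance measurement
  columns (`v.0`, `v.1`, …).
* **Genetics**: independent SNPs with dosages Binomial(2, MAF), normal
  per-SNP weights, and a standardized polygenic score entering the hazard.
* **Event times**: exponential (Weibull shape 1) proportional-hazards
  times with linear predictor $\sum_v \beta_v X_v + \beta_{PRS}\,PRS +
  \beta_{age}(age-55) + \beta_{sex}\,male$; administrative censoring at
  the end of follow-up plus independent exponential random censoring with
  rate $-\log(1-c)/\tau$ so a fraction $c$ is lost over the window in the
  absence of events — standard survival-simulation practice.
* **Blood-assay analogues** (lymphocyte %, neutrophil %, total
  bilirubin) driven partly by disease status and partly by the exposure
  burden, so both mediation model sets have true signal.

Defaults are chosen to resemble the motivating study's data structure:
baseline hazard 6e-4/person-year over 12 years of follow-up gives
roughly 0.7% cumulative incidence, the order observed for PD in a
middle-aged cohort; ages are uniform on 40–69 and ~53% of participants
are female. Sample size, effect sizes and the baseline hazard are the
user's dials; the test suite raises the event rate where power is needed
and states each size explicitly.

All randomness derives from one master seed through a fixed counter
scheme (`child_seed()`), so each stage is independently reproducible and
two runs with the same configuration are bit-identical.

**What the generator does not emulate.** Linkage disequilibrium,
realistic minor-allele spectra, field-ID naming, non-proportional
baseline effects (unless requested via the PH-violation helpers in the
tests), informative censoring, and measurement error beyond the
instance-level noise. Passing tests therefore demonstrate correctness of
the estimation machinery under the stated generative assumptions, not
robustness to every property of real cohort data.

### The ground-truth record and the generative PAF

`generate_cohort()` returns a truth record with the true coefficient
vector, the polygenic score, each participant's linear predictor and
hazard, and a *generative PAF* per scoreable domain and counterfactual
model. The generative PAF is built independently of the estimation code:
oriented true risk indicators (median splits for continuous variables,
complementation for protective binaries, with the analytic indicator
weight $\log[\Phi(|b|)/\Phi(-|b|)]$ for a median-split standard-normal
exposure), a true weighted score, tertiles, and the binary exposure
contrast of each model. Its hazard ratio is the **large-n limit of the
Cox coefficient**: the root of the expected partial-likelihood score
under the true individual hazards and the configured censoring, computed
on a 400-point time grid. Defining the truth as the estimand's limit —
rather than, say, a person-time incidence-rate ratio — makes the
end-to-end recovery test a like-for-like comparison; the two definitions
differ by a few percent once cumulative incidence is appreciable,
because the partial likelihood weights risk sets differently.

The recovery test runs at n = 100,000 with `rho = 0` and null age/sex
effects. Both choices are about keeping the oracle well-posed, not about
difficulty: with correlated exposures, null variables that share a
domain's latent factor are *marginally* associated with disease and are
legitimately selected by the scan at large n, so the pipeline's factor
set no longer matches the truth record's contrast; and with non-null
adjusters the adjusted Cox estimand is conditional while the analytic
truth is marginal. Under the aligned conditions the pipeline's
unweighted domain PAFs agree with the generative values to well under
one percentage point.

## Preprocessing conventions

* Recoding first: −10 → 0.5 in count-coded variables, −1/−3 → missing
  everywhere (idempotent); then instance averaging over non-missing
  instances; then exclusions; then imputation; then dummy coding. The
  order is a documented choice — imputing after exclusion means the
  missingness thresholds act on raw missingness.
* Exclusions are disjoint by first-matching criterion (prevalent
  disease, missing genetics, excess missingness) and use strict
  inequalities: a participant or variable missing *exactly* 20% is
  retained.
* Imputation: mode for categorical/binary/ordinal (ties broken by the
  smallest coded value), median for continuous, both computed on the
  post-exclusion cohort.
* Dummy coding: each k ≥ 3-level unordered categorical becomes k−1
  indicators against the most frequent level — the reference choice
  stabilizes the Cox fits and is otherwise arbitrary; ordinal variables
  stay integer-coded; constants are dropped with a warning.

## The exposure-wide scan

Each modifiable (encoded) variable is fitted in its own Cox model with
age, sex and assessment center as adjusters (center as a categorical
covariate, not strata — with few centers the two are practically
equivalent and covariates keep a single baseline hazard). Significance
is declared at `alpha / m` with `m` the number of scanned variables;
subgroup scans reuse the full-sample threshold so significance marks are
comparable across strata.

Proportional hazards is checked per exposure by the score test for zero
slope of the scaled Schoenfeld residuals against Kaplan–Meier-transformed
time (`survival::cox.zph`; the KM transform is a robust default under
censoring). Exposures failing at $\alpha = 0.05$ are refit with an
additional $x\cdot\log t$ term, and the reported effect is the
time-varying effect $\beta + g^*\beta_t$ evaluated at the
information-weighted center of follow-up, $g^* = -V_{12}/V_{22}$
(clipped to the observed range of $\log t$ over event times), with a
delta-method standard error. The evaluation point matters: the refit is
only run for exposures *selected* by the PH test, and an effect
evaluated at, say, the mean event time is correlated with the selected
slope, which measurably inflates the scan's family-wise error rate; at
$g^*$ the reported effect is asymptotically uncorrelated with the
interaction coefficient and the p-value stays calibrated (verified by
the global-null simulation in the test suite). The refit
episode-splits follow-up at event times; when
the number of distinct event times exceeds the resolution cap (100 for
the standalone function, 20 inside the scan, where hundreds of refits
may occur) an event-time quantile grid is used and $\log t$ is evaluated
as a step function at each interval's upper boundary, so that every
member of a risk set sees the same evaluation time — evaluating at each
episode's own end time instead would bias the interaction coefficient.

For throughput, the scan fits each exposure through
`survival::coxph.fit` on a shared design-matrix skeleton and reassembles
a `coxph`-classed object for `cox.zph`; a unit test asserts bit-identical
agreement with the plain `coxph` route.

Collinear significant hits (Pearson r² > 0.9 on the encoded columns) are
pruned by iteratively dropping the member of the worst pair with the
larger scan p-value — the smaller p-value carries more evidence and the
choice is deterministic.

## Composite scores, joint models, gene–environment grids

Only five domains are scoreable; early-life and local-environment
variables are scanned but never scored. Orientation produces all-binary
risk indicators; continuous factors are median-dichotomized in the risk
direction (the score formula consumes binary inputs, and the median
split is the least arbitrary single cut). The weighted score
$S = \sum_k X_k\beta_k / \sum_k \beta_k$ uses β from the within-domain
multivariable Cox fit; a coefficient that turns negative under mutual
adjustment is retained with sign (and flagged), preserving the score
formula exactly. Tertiles (favorable/moderate/unfavorable) cut at the
1/3 and 2/3 type-7 quantiles with ties going to the lower category, so
labels are a deterministic function of the scores. Both weighted and
unweighted tertiles are computed; the unweighted variant backs the
sensitivity analyses.

The joint model enters all five domain categories (favorable reference)
plus adjusters in one fit. The gene–environment grid crosses PRS
tertiles with score tertiles (nine groups, low-PRS/favorable reference)
and, within each PRS stratum, contrasts favorable and moderate against
an unfavorable reference; genotype batch, when supplied, joins the
adjusters.

## Mendelian randomization

Instruments are SNPs with exposure p < 5e-8, relaxed to 5e-6 when fewer
than `min_snps = 3` survive (the threshold defining "insufficient" is a
package choice). Per-SNP Wald ratios use first-order delta-method
standard errors, `se_out/|beta_exp|`. IVW is the fixed-effect weighted
mean; Cochran's Q tests homogeneity against it. The weighted median
interpolates the inverse-variance-weighted CDF at 50% with a parametric
bootstrap SE (1,000 draws, fixed seed). MR-Egger regresses outcome on
exposure betas with an intercept (weights `1/se_out²`) after orienting
exposure betas positive; inference is t-based on K−2 degrees of freedom.
LD clumping, allele harmonization and outlier-removal diagnostics are
out of scope; the synthetic SNPs are generated independent, and
heterogeneity/pleiotropy diagnostics are carried by Q and the Egger
intercept.

## Mediation

The difference method: total effect from `outcome ~ exposure +
covariates`, direct effect from the same model plus the mediator,
mediation = total − direct — an identity that holds exactly in every
bootstrap draw, which is why the difference method (rather than the
product of coefficients; the two coincide for linear models) was chosen.
Inference is a percentile bootstrap over participants (default 1,000
draws, fixed seed); the p-value is twice the smaller tail proportion of
draws on either side of zero. When disease is the outcome (the second
model set) the decomposition runs on a linear probability model, keeping
the identity exact; logistic-scale decomposition is a non-goal.

## Attributable fractions

Levin's formula $PAF = P(HR-1)/(P(HR-1)+1)$ is applied to two
counterfactuals per domain: model 1 contrasts the unfavorable tertile
against the rest (prevalence ≈ 1/3 under balanced tertiles), model 2
contrasts unfavorable + moderate against favorable (≈ 2/3). The HR comes
from the adjusted Cox fit of that binary contrast.

Weights are PCA communalities: eigen-decomposition of the correlation
matrix of the standardized weighted domain scores, Kaiser retention with
an *inclusive* eigenvalue ≥ 1 rule (so an exactly-identity correlation
matrix keeps all components rather than dropping everything), and
communality = sum of squared loadings on retained components. The
per-domain weighted PAF is `unweighted × sqrt(communality)`; the square
root is the weighting that reproduces every cell of the published
reference table from its printed inputs, so it is adopted as the
package's convention. The overall weighted PAF **rounds each per-domain
value to two decimals before summing** — the reference overall values
are only reproduced under that rounding convention, making it part of
the reporting contract. Whether the published analysis ran its PCA on
the five domain scores or on the individual factors is not stated; the
package defaults to the domain scores and offers per-model binary
exposure indicators behind `communality_on = "indicators"` (which also
explains why reference communalities can differ between models).
PAF confidence intervals are a non-goal.

## Numerical choices and degenerate inputs

* Tertile cuts: type-7 sample quantiles, ties to the lower category;
  constant score vectors are an error.
* A domain whose score admits fewer than three occupied tertiles (e.g. a
  single binary member) degenerates: the affected contrast errors, and
  `paf_report()` records an `NA` row with a warning rather than failing
  the whole report.
* Constant covariates and monotone partial likelihoods error with the
  covariate named; the scan records these per variable and continues.
* PRS standardization uses the sample SD (n−1); zero variance is an
  error.
* The mediation bootstrap warns below 100 draws; collinear
  exposure/mediator designs are an error (rank check).

## Problem sizes used by the test suite

The suite is sized for a single CPU: a 200-replicate family-wise-error
simulation of the full 255-variable scan at n = 2,000; 200-replicate
coverage and Schoenfeld-size checks at n = 400–500; the end-to-end
generative-PAF recovery at n = 100,000; and unit fixtures at
n = 300–6,000. Together these run in roughly a quarter of an hour.

## Known limitations

* The scan is marginal per exposure; with correlated exposures it flags
  proxies of causal variables (by design — the collinearity filter and
  MR stage exist to triage them).
* Additive per-domain Levin PAFs can exceed 100% under strong effects;
  multiplicative combination is a non-goal.
* The Cox machinery assumes non-informative censoring and no left
  truncation; stratified baselines and frailty models are out of scope.
* MR results are only as good as the summary statistics supplied; the
  bundled generator satisfies the InSIDE assumption by construction.
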