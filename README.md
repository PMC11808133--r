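# exposcan

Exposure-wide survival scans, composite domain risk scores, and
population-attributable-fraction (PAF) estimation for incident disease in
biobank-style cohorts, with Parkinson's disease (PD) as the motivating
outcome.

Large prospective cohorts record hundreds of modifiable baseline
exposures — socioeconomic, medical, psychosocial, anthropometric,
early-life, environmental and lifestyle variables — alongside genotypes
and years of follow-up. `exposcan` implements the full analysis chain a
hypothesis-free risk-factor study of such a cohort needs, and ships a
synthetic cohort generator with known ground truth so every stage is
testable without access to restricted data.

## What it computes

* **Exposure-wide association scan.** One Cox proportional-hazards model
  per exposure, adjusted for age, sex and assessment center, with a
  Bonferroni threshold `alpha / m` (0.05/255 = 1.96e-4 at the motivating
  study's scale), Schoenfeld-residual checks of proportional hazards, a
  time-interaction refit (`x * log t`) where the assumption fails,
  collinearity filtering at r² > 0.9, and subgroup replication.
* **Polygenic risk score.** `PRS_j = (Σ_i β_i G_ij − mean) / SD`, with
  tertile stratification.
* **Composite domain risk scores.** Significant factors are oriented so
  that 1 means risk (protective binaries complemented, continuous factors
  median-split), then combined per domain either unweighted (count of
  risk factors) or weighted, `S = Σ X_k β_k / Σ β_k`, with β from the
  within-domain multivariable Cox model; tertiles are labelled
  favorable / moderate / unfavorable.
* **Gene–environment stratification.** A 3×3 grid of PRS tertile × score
  tertile hazard ratios against the low-PRS/favorable reference, plus
  within-stratum contrasts.
* **Two-sample Mendelian randomization.** Instrument selection at
  p < 5e-8 (relaxing to 5e-6 when SNPs are scarce), inverse-variance
  weighted, weighted-median and MR-Egger estimators, Cochran's Q and the
  Egger intercept.
* **Mediation.** Difference-method decomposition (`mediation = total −
  direct`, exact by construction) with percentile-bootstrap inference.
* **Attributable fractions.** Levin's formula
  `PAF = P(HR−1) / (P(HR−1)+1)` per domain under a conservative
  (remove unfavorable) and an optimistic (remove unfavorable + moderate)
  counterfactual, weighted by the square root of each domain's PCA
  communality (Kaiser retention, eigenvalue ≥ 1), and summed — after
  rounding each per-domain value to two decimals — into an overall
  weighted PAF per model.

## Worked example

```r
library(exposcan)

cfg <- cohort_config(
  n = 20000, baseline_hazard = 0.01,
  true_log_hr = c(med_cont1 = 0.5,  med_bin2 = 0.4,
                  psy_cont1 = 0.45, psy_bin2 = 0.35,
                  ses_cont1 = 0.35, ses_bin2 = 0.35,
                  phy_cont1 = -0.5, phy_bin2 = 0.45,
                  lif_cont1 = 0.4,  lif_bin2 = -0.35),
  seed = 2026)
sim  <- generate_cohort(cfg)
scan <- collinearity_filter(run_scan(sim$cohort, sim$catalog), sim$cohort)
print(scan, n = 5)
#>   variable               domain       beta        hr             p
#>  med_cont1      medical history  0.4368995 1.5479005 6.726925e-179
#>  psy_cont1 psychosocial factors  0.4095375 1.5061210 8.095675e-169
#>  phy_cont1    physical measures -0.3670699 0.6927612 6.923900e-130
#>  ses_cont1 socioeconomic status  0.3187911 1.3754640 2.628213e-108
#>  lif_cont1            lifestyle  0.2980632 1.3472470  1.147767e-91
```

All ten planted effects are recovered (the protective grip-strength-like
factor `phy_cont1` with HR < 1, the rest adverse); two of them violated
proportional hazards and were automatically refit with the
time-interaction fallback. Scores and PAFs then follow:

```r
oriented <- orient_factors(scan, sim$cohort, sim$catalog)
scores   <- build_domain_scores(oriented, sim$cohort)
paf_report(sim$cohort, scores)
#>               domain model p_pop    hr unweighted_paf communality weighted_paf
#>      medical history     1 0.249 1.933        18.8511      0.5082      13.4387
#>  psychosocial factors     1 0.244 1.778        15.9767      0.5196      11.5169
#>  ...
#> Overall weighted PAF: model 1 = 62.56%, model 2 = 126.23%
```

Per domain and model this reads: the fraction of participants exposed
(`p_pop`, the unfavorable tertile for model 1), the adjusted hazard
ratio of that contrast, Levin's unweighted PAF in percent, the domain's
PCA communality, and the communality-weighted PAF. The planted effects
here are deliberately strong, so the summed Levin fractions exceed what
observational cohorts show (additive per-domain PAFs are not bounded by
100%); at realistic effect sizes the overall weighted PAF lands in the
tens of percent.

The whole chain — generation, preprocessing of raw special codes
(-1/-3 → missing, -10 → 0.5), imputation, dummy coding, scan, scores,
gene–environment grid, mediation, MR and PAF — also runs as one command:

```r
run_pipeline(cfg, outdir = "run1")
```

which writes per-stage CSV/JSON outputs and a `manifest.json` with seeds
and checksums; identical configurations reproduce byte-identical outputs.

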