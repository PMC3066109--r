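---
title: "Methods: marker augmentation of a Framingham-style MI risk model"
author: "riskreclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker augmentation of a Framingham-style MI risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskreclass)
```

`riskreclass` answers one question end to end: when a candidate risk
marker is added to a Framingham-style Cox model of incident myocardial
infarction (MI), does prediction improve? This vignette is the package's
account of the statistical machinery, the choices that were genuinely
open, and what the simulation-based tests do and do not establish.

## Cohort contract and covariate coding

The unit of input is a participant-level table (CSV dialect documented in
`?read_cohort`) with baseline measurements, two SNP genotypes stored as
risk-allele counts, follow-up time in years and an MI indicator. Storing
risk-allele *counts* rather than raw genotypes deliberately sidesteps
strand and allele-labelling ambiguity: whichever allele the file counts is
the risk allele.

The analysis cohort is produced by a set-union exclusion cascade
(`apply_exclusions`): baseline MI, baseline stroke, race recorded as
neither white nor black, or missing data in any model field. The rules
overlap; the ledger reports per-rule counts and the union separately, and
the operation is idempotent and order-independent. Missing-data handling
is complete-case removal throughout — the package does no imputation, so a
participant lacking any covariate, marker or outcome field is excluded.
DNA availability is not a separate field of the cohort dialect; samples
without genotypes simply carry missing allele counts and fall under the
missing-data rule.

Coding follows the Framingham risk-score conventions:

* LDL-C: left-closed bins [0,100), [100,130) (reference), [130,160),
  [160,190), [190,Inf) mg/dL.
* HDL-C: [0,35), [35,45), [45,50), [50,60), [60,Inf) mg/dL; the reference
  band is sex-specific (45–49 men, 50–59 women), which is why design
  matrices are built per sex.
* Blood pressure: the source tables name the categories (optimal, normal,
  high-normal, HTN stage I, stage II–IV) without printing cutoffs; we
  adopt the JNC-V bands used by the original Framingham score —
  SBP <120/120–129/130–139/140–159/≥160, DBP <80/80–84/85–89/90–99/≥100 —
  and assign each participant the *higher* of the two implied categories.
  Categories are coded from measured pressures only; antihypertensive
  medication is not part of the cohort contract.
* Markers: the 9p21.3-like SNP enters additively (allele count), the
  KIF6-like SNP dominantly (carrier indicator), and CRP continuously,
  divided by the *sex-specific sample SD* so its coefficient is per SD.
  CRP is used untransformed (no log), because the effect size the model
  targets is stated per SD of CRP itself.

## Cox fitting

`fit_cox` maximises the Breslow-ties log partial likelihood by
Newton–Raphson with step-halving. Breslow tie handling (rather than Efron
or exact) matches the era's default in the major survival software and has
a simple closed form that an independent oracle can enumerate. Numerical
choices, all fixed:

* covariate columns are centered at their sample means before iteration,
  and the linear predictor is shifted by its maximum before
  exponentiation; both are exact (they cancel in the likelihood) and guard
  against overflow;
* convergence when max |score| < 1e-8 or the Newton step is below 1e-10,
  with a 30-iteration cap;
* a rank check (QR of the centered design) rejects collinear designs
  before iteration, and a near-singular information matrix aborts with an
  error rather than a silent pseudo-inverse;
* monotone likelihoods (perfect separation) are detected by a coefficient
  magnitude guard at |beta| > 50; note that a separation whose score
  vanishes numerically below that magnitude converges "successfully", as
  it does in standard fitters — the guard bounds the damage rather than
  diagnosing separation per se;
* the covariance is the inverse observed information at the optimum;
  Wald CIs use the normal 0.975 quantile.

With all coefficients at zero the Breslow cumulative baseline hazard
reduces exactly to the Nelson–Aalen estimator; the tests exploit a small
dataset whose score vanishes at zero to pin this down by hand.

## Ten-year risk

`breslow_baseline_survival` accumulates `H0(t)` over distinct event times
with denominators evaluated at the *centered* linear predictor, so
`S0 = exp(-H0(horizon))` is the survival of the mean-covariate
participant, and `predict_t_year_risk` computes
`1 - S0^exp(beta'(x - xbar))`. Whether to center is a real convention
choice (raw linear predictors shift `S0` correspondingly and the risks are
identical in exact arithmetic); centering follows the published
Framingham risk-function recipe, is numerically stabler, and is recorded
in the serialized fit so a consumer knows which convention the stored
`S0` assumes. A horizon beyond the last observed time holds `H0` at its
last value and warns.

Death before MI is treated as censoring, not as a competing risk; the
estimated "10-year risk" is therefore the cause-specific-hazard quantity
the Framingham score reports, which overstates absolute risk in an
elderly cohort with substantial competing mortality. A Fine–Gray or
Aalen–Johansen treatment is deliberately out of scope.

## Reclassification metrics

Predicted risks are grouped into the left-closed categories 0–<5%,
5–<10%, 10–<20%, ≥20% (so 5% belongs to the second category, 20% to the
fourth). `nri` computes the categorical NRI and its asymptotic z-test
from the paired 4x4 event and non-event tables; when nobody moves, the
NRI is 0 with p = 1 by convention. `compare_auc` implements DeLong's
structural-components variance for the paired AUC difference, computed
from midranks so heavily tied risk scores are handled exactly; it agrees
with `pROC::roc.test` to machine precision and with a stratified
bootstrap within Monte-Carlo error.

Two conventions deserve emphasis because the underlying reports are
ambiguous about them:

* **Case definition.** A participant is a case if an MI occurred at any
  time during follow-up (median well beyond the 10-year horizon);
  participants censored early without MI are controls. This mixes
  follow-up lengths into a fixed-horizon classification problem — the
  time-honoured practice the package mirrors — and is recorded in the
  report metadata. Kaplan–Meier-weighted (censoring-adjusted) NRI/AUC
  variants are out of scope.
* **AUC p-value.** The per-row p-value tests the *difference* between the
  augmented and base AUCs (DeLong), not the augmented AUC itself.

P-values in the report are unadjusted; the JSON metadata carries a note
to that effect rather than imposing any particular multiplicity
correction.

## The synthetic-cohort generator

`sim_config()` defaults encode the marginal structure of the white
stratum of the motivating elderly cohort: 1495 men and 2156 women; age
73.3 (5.7) / 72.3 (5.4) years truncated at the 65-year entry criterion
(the latent mean is shifted so the *observed* mean hits the target);
smoking 10% / 12%; diabetes 13% / 8%; LDL 124 (33) / 135 (37); HDL
48 (13) / 59 (16) mg/dL. Values the source tables do not print are the
package's own documented assumptions:

* blood-pressure means/SDs (135/21 and 71/11 mmHg men; 134/21 and 70/11
  women) were chosen so the five JNC-V categories are all well populated
  in roughly the reported proportions;
* CRP is lognormal with meanlog 0.4553, sdlog 1.0 — calibrated so 26% of
  the population exceeds 3 mg/L, the published elevated-CRP prevalence
  for this cohort;
* allele frequencies 0.5 and 0.408 are back-solved under Hardy–Weinberg
  from the reported ~75% and ~65% carrier fractions
  (`1 - (1-q)^2 = carrier fraction`);
* the baseline MI hazard (0.010/person-year men, 0.006 women for the
  mean-covariate participant) is an assumption — no incidence rate is
  printed for the analysis cohort — chosen to give the familiar ~10–15%
  event fraction over ~13 years in men;
* the death (competing censoring) rate defaults to 0.045/person-year and
  administrative censoring to 16.5 years (an enrollment-to-cutoff
  window); `calibrate_followup` bisects the death rate to hit a target
  median time at risk of 12.6 years.

True effects enter the event process through an exponential event time
with rate `base_hazard * exp(lp)`, where `lp` applies the configured
log-hazard-ratios to mean-centered age, diabetes and the three markers —
by default the sex-specific estimates the analysis is designed to
recover (men 1.22/1.42/1.28, women 1.16/1.05/1.15) with age 1.044/year
and diabetes exp(0.57)/exp(0.66). Smoking and the lipid/BP categories
carry no true effect by default; they are noise covariates that the
fitted model still estimates, which is exactly the situation the base
model faces in practice.

Covariates are drawn independently — the source provides only marginals,
and marginals are all the downstream metric tests require. Real lipid,
blood-pressure and CRP values are correlated; consequently, passing
recovery tests here demonstrates correctness of the estimators under the
stated generating model, not robustness to confounding structure. The
generator also has no linkage disequilibrium, population stratification
or CRP measurement-error model.

Calibration detail: the median follow-up of a single 10000-person cohort
has Monte-Carlo standard error of roughly 0.18 years under these
settings, so `calibrate_followup` evaluates each candidate death rate as
the *mean of 20 replicate cohort medians* (common random numbers across
rates keep the objective monotone, so bisection converges); the
calibrated configuration's true median then sits within a few hundredths
of a year of the target, while any single realised cohort still scatters
around it with that ~0.18-year spread.

## Problem sizes in the test suite

The suite exercises: exact-oracle equivalence of the Cox fitter against
grid search and `survival::coxph` on datasets of n <= 30; brute-force
counting oracles for the reclassification table, NRI and AUC; DeLong
against `pROC` and a 2000-replicate bootstrap at n = 60; consistency of
beta-hat at n in {500, 2000, 8000}; recovery of the generating hazard
ratios with 200 replicates of 1495-man cohorts (mean HR within 5% of
truth, 95% CI coverage in [0.92, 0.98]); size of the NRI z-test under a
null marker with 2000 replicates of n = 600 (rejection rate in
[0.03, 0.07] at alpha = 0.05); and generator calibration (carrier
fractions at n = 10^4, median follow-up after calibration). These sizes
were chosen as the smallest at which the Monte-Carlo error of each check
is comfortably below its acceptance band.

## Known limitations

* Cause-specific hazards only; no competing-risk absolute risk.
* Categorical NRI only; no continuous NRI, IDI or time-dependent ROC.
* The asymptotic NRI z-test is anti-conservative in some regimes
  (estimated categories, weak base models); under the package's null
  simulation its size is close to nominal, but that is a
  statement about these settings, not a general guarantee.
* Complete-case analysis; informative missingness would bias every
  downstream quantity.
* The generator's independence assumptions mean simulated AUCs are not
  calibrated to any real cohort's discrimination; only effect-recovery
  and test-size properties transfer.
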