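---
title: "Individualized survival gain from adjuvant therapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized survival gain from adjuvant therapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After esophagectomy for esophageal cancer, should a given patient receive
adjuvant (post-operative) chemo- and/or radiotherapy? Observational
registries record which patients did receive it and how long they lived,
but treatment was assigned by clinical practice, not at random: deeply
invasive, node-positive cancers were far more likely to get adjuvant
therapy than early-stage disease. Population-average comparisons therefore
confound treatment with prognosis, and — more importantly — the benefit
plausibly differs across the pathologic tumor (pT) by nodal (pN) staging
grid: what helps a pT4N3 cancer may harm a pT1N0 one.

`survtwin` implements an individualized analysis of this question in four
stages, run separately for adenocarcinoma and squamous cell carcinoma:

1. **Eligibility (virtual equipoise).** A probability forest models
   P(adjuvant | covariates); each patient's probability is estimated
   out-of-bag. Patients outside a configurable band (default
   [0.10, 0.90]) — profiles that in observed practice essentially never or
   essentially always received adjuvant therapy — are excluded, because no
   fair like-for-like comparison exists for them. The audit reports the
   observed treatment rate inside the excluded tails.
2. **Survival analysis.** A random survival forest is grown on the
   eligible patients using a design with every covariate `x`, the
   treatment indicator `Z`, and every product `Z·x` (width 2p + 1). The
   interaction columns let individual trees carve out regions where the
   treatment effect differs.
3. **Virtual twins.** Each patient is predicted twice: once as treated and
   once as untreated, flipping `Z` and recomputing all `Z·x` columns while
   leaving the covariates untouched. The patient is their own control.
4. **Lifetime accounting.** The gain or loss is the difference in
   restricted mean survival time (RMST) — the area under each predicted
   survival step-curve up to τ = 120 months — in months of expected
   lifetime within 10 years. Results are summarized per pT × pN cell by
   quartiles, 1.5-IQR whiskers, predicted 5-year survival per arm, and a
   benefit class (detriment / insignificant / meaningful, default
   threshold 4 months).

## The survival forest

The engine (`rsf_fit()`, in C++) follows the standard random survival
forest recipe: each tree bootstraps the rows; nodes are split to maximize
the standardized log-rank statistic over `mtry` random columns, with
candidate cutpoints at midpoints of sorted unique in-node values (at most
`n_cutpoints = 32` random candidates per column); splitting stops below
`min_node_deaths` unique death times; terminal nodes store the
Nelson–Aalen cumulative hazard of their in-bag members, with deaths
preceding censorings at tied times. The ensemble predicts on the
cumulative-hazard scale, `S(t) = exp(−H̄(t))`, averaging terminal-node
hazards across trees on the union grid of event times (step
interpolation). Out-of-bag ensemble mortality (the hazard summed over the
grid) yields the reported out-of-bag concordance.

Defaults: `ntree = 500`, `mtry = ⌈√p⌉`, `n_cutpoints = 32`,
`min_node_deaths = 15` for a plain prognostic forest. The virtual-twin
forest (`fit_vt_forest()`) defaults to `min_node_deaths = 10`: detecting
treatment-covariate interactions requires deeper trees than pure risk
prediction, and in validation against generator ground truth the
15-death default failed to localize the effect reversals in the small pT4
cells while 10 recovered them.

**Out-of-bag twins.** Both the factual and the counterfactual curve of a
patient are predicted using only the trees whose bootstrap sample excluded
that patient. Predicting the counterfactual with *all* trees looks
natural (the flipped row was never a training row), but the flipped row
shares all of the patient's covariates, so trees grown on the patient
route it to the patient's own neighborhood and pull the counterfactual
toward the factual outcome; in validation this contaminated per-patient
deltas measurably. Scoring both twins on the identical out-of-bag
sub-ensemble removes the contamination and cancels shared ensemble noise
in the difference. The all-trees variant remains available
(`twin_curves(..., counterfactual = "all")`).

**The treatment-probability forest** (stage 1) deliberately uses sharper
settings than a prediction forest would (`mtry` of two thirds of the
columns, minimum node size 2): overlap trimming needs resolution in the
probability *tails*, and heavily decorrelated, coarse-leaved probability
trees shrink extreme profiles toward the marginal treatment rate — a
profile treated 99% of the time can score 0.85 and escape trimming. The
probabilities remain honest because every patient is scored out-of-bag.

A design alternative we rejected: two per-arm forests instead of one
interaction forest. The single forest matches the method's published
form, shares the baseline-hazard structure between arms, and lets the
data decide where treatment matters; per-arm forests double the variance
precisely in the sparse-arm regions that are hardest anyway.

## The synthetic cohort generator

No public individual-level registry of this kind exists, so validation
uses `generate_cohort()`, which draws cohorts with the statistical
structure the analysis must cope with, plus closed-form ground truth:

* ordinal pT (Tis < T1 < … < T4) with pN drawn conditionally on pT
  (positively associated), pM and resection margin linked to stage;
  age, sex, grade, tumor location, weight loss and comorbidity count as
  additional covariates (some prognostic, some pure noise);
* confounded assignment: logit P(Z = 1) = α₀ + αT·pT + αN·pN + αM·M1 with
  default α = (−3.1, 0.6, 0.7, 0.4), giving a strong practice gradient
  (treatment probability ≈ 0.05 in T1N0 vs ≈ 0.8 in T4N3);
* exponential survival, log-hazard linear in stage, margin, age and
  comorbidities (baseline 0.0045/month ⇒ 5-year survival ≈ 76% for the
  reference TisN0 patient, ≈ 1% for T4N3, matching published stratum
  survival); the treatment multiplies the hazard by exp(γ(pT, pN));
* uniform administrative censoring on (6, 130) months; missing staging
  completely at random (pN 5%, pT 0.5%, echoing registry "X" rates).

Exponential survival is the deliberate choice over Weibull or piecewise
hazards: RMST is then available in closed form,
RMST(λ, τ) = (1 − e^{−λτ})/λ, so every patient's true individual
treatment effect is exact, not simulated.

The `paper_like_preset()` effect maps reproduce the qualitative clinical
pattern: for adenocarcinoma, benefit (γ < 0) only in the pT4 row and pN3
column, harm (γ > 0) in pT1–3 N0, and no effect in the N1–2/T1–3 belt;
for squamous cell carcinoma, benefit in pT3–4 N0 and pT2–4 N1–3, harm in
pTis–1 N0. Magnitudes were chosen so every nonzero cell's stratum-median
true effect lies in roughly ±4–15 months at τ = 120 (verified
empirically, since within-stratum age/margin/comorbidity spread shifts
the median off the analytic value).

**What the generator does not emulate:** institution and era effects,
informative censoring, non-proportional hazards, staged treatment
decisions over time, and misclassified staging. Passing validation here
shows the pipeline recovers known effects under its own assumptions; it
does not certify performance on real registry data.

## Imputation

Missing staging covariates are imputed before modelling by iterative
forest imputation (missForest-style): initialize with mode/median, then
cyclically regress each incomplete covariate on the others (plus the
always-complete treatment indicator) with a 100-tree forest, refreshing
imputed cells until the mean normalized change drops below 1e-3 or 5
sweeps. Outcome fields are never imputed nor used as predictors — the
published analyses impute inside the outcome forest ("on the fly"), but
decoupling imputation from the survival model keeps each stage testable
and avoids leaking the outcome into the effect estimates. Observed cells
are never altered; covariates more than 90% missing fall back to
mode/median with a warning.

## Numerical choices

* RMST integrates the right-continuous step curve exactly: S = 1 before
  the first event time, last value extended to τ.
* 5-year survival is S(60) evaluated right-continuously.
* Quartiles use linear interpolation of order statistics (R type 7);
  whiskers are the most extreme points within 1.5 IQR of the quartiles.
* Log-rank variance terms with risk set 1 are dropped; a zero-variance
  split scores 0 (uninformative).
* Ties: deaths precede censorings at equal times.
* Benefit classes: median < 0 ⇒ detriment; < 4 months ⇒ insignificant;
  ≥ 4 ⇒ meaningful. The 4-month default mirrors the clinical reading in
  which ~2-month medians are called no meaningful benefit and ~4.4+ are
  called benefits; it is configurable.
* One global seed fans out to per-stage seeds by fixed offsets, so any
  stage can be re-run in isolation bit-identically.

## Validation protocol and its limits

The test suite validates each stage against independent oracles
(brute-force log-rank tabulation, hand-computed Nelson–Aalen and
reverse-Kaplan–Meier toys, the exponential RMST closed form) and the
whole pipeline against generator ground truth. Problem sizes are chosen
for a desk-scale run: null-calibration and recovery checks use cohorts of
n = 4000 with 300–1000 trees; recovery pools three independent cohort
replicates per histology and compares pooled per-patient estimates and
pooled stratum medians (minimum pooled stratum size 60) with the
closed-form truth. Null-effect calibration likewise pools five cohort
replicates before taking the median months gained/lost: a single
cohort's median carries ~1.5 months of realization noise even under a
perfectly calibrated estimator, and the quantity of interest is the
estimator's central tendency, not one draw.

Two limits are worth stating plainly. First, per-patient delta estimates
are noisy; with a large zero-effect belt in the truth, the attainable
rank correlation between estimated and true individual effects sits
around 0.3–0.5 per replicate. Second, in small strata (20–60 patients
with |γ| ≈ 0.3) the *realized* finite-sample effect flips sign in a
non-trivial fraction of cohort draws — a within-cell Cox fit on the raw
generated data flips exactly where the forest "fails", and ranger's
survival forest on the identical design shows the same behavior — so
per-cell sign recovery from a single realization is capped for any
estimator. Pooling replicates mitigates but does not abolish this.
These are properties of the statistical problem at this scale, and they
temper how much a stratum-level table from one cohort of this size should
be trusted — synthetic or real.
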