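---
title: "Methods: mural-lesion risk scoring and diagnostic strategy economics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mural-lesion risk scoring and diagnostic strategy economics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muralrisk)
```

## The problem

In potential small bowel bleeding (PSBB) the two main noninvasive tests are
complementary: video capsule endoscopy (VCE) has high yield for mucosal
lesions (angiodysplasia, ulcer/inflammation) but misses a substantial share
of mural-based lesions (small-bowel tumors), while CT enterography (CTE) has
the opposite profile. `muralrisk` implements (a) a logistic score that
predicts, from five routine variables, whether a PSBB patient's bleeding
arises from a mural-based lesion, (b) the pipeline that derives and validates
such a score, and (c) an expected-value decision model that quantifies what
using the score as a triage rule does to missed lesions, test counts and
cost.

## The risk model

The score is an ordinary logistic regression on the percent scale:

$$P = 100 \cdot \frac{1}{1 + e^{-\eta}}, \qquad
\eta = \beta_0 + \beta_1\,\text{age} + \beta_2\,\text{atherosclerosis} +
\beta_3\,\text{CKD} + \beta_4\,\text{antiplatelet} + \beta_5\,\text{albumin}.$$

Defaults in `mural_model()` are $\beta = (-3.7207,\ -0.00696,\ -1.0531,\
-0.6161,\ -0.8276,\ +0.8627)$ with cutoff 24.2%. Age is in years, albumin in
g/dL, the three flags are 0/1. The signs encode the epidemiology: advanced
age, atherosclerosis, chronic kidney disease and antiplatelet use predispose
to mucosal angiodysplasia and small-bowel mucosal injury (hence *lower*
mural probability), while tumors occur in younger patients with preserved
albumin.

Probabilities are carried in percent throughout the public API (matching how
such scores are used clinically); they are converted to $[0,1]$ only inside
likelihood computations. Classification uses the $\ge$ rule so the published
cutoff itself is actionable; the tie therefore classifies as mural.
Validation is strict — a missing predictor or a non-binary flag is an error,
never imputed — because the derivation design excluded incomplete records,
and silent imputation would change the estimand.

## Derivation pipeline

`derive_mural_model()` reproduces the derivation procedure:

1. **Split**: seeded permutation, prefix of `round(n * fraction)` rows. The
   default fraction is 0.7 (the conventional allocation); any realized
   historical split is reachable by passing its exact fraction (e.g. 0.662
   yields 196/100 at $n = 296$).
2. **Univariate screen**: one single-covariate logistic fit per candidate;
   odds ratio $e^{\hat\beta}$, Wald 95% CI $e^{\hat\beta \pm 1.96\,SE}$ and
   Wald p-value. Wald (not profile) intervals are used deliberately: they
   have the familiar OR ± shape and they make separation visible instead of
   hiding it — a covariate with zero exposed cases is reported as
   *not computable* rather than with an absurd interval.
3. **Multivariate fit** of the univariately significant covariates
   ($p < 0.05$), reported in the same table shape.
4. **Final model**: a refit of the five *prespecified* covariates regardless
   of multivariate significance. This mirrors the design choice that
   univariately significant, clinically meaningful predictors stay in the
   model even when multivariate parsimony would drop them.
5. **Cutoff**: Youden-optimal threshold ($\max J = \text{sens} +
   \text{spec} - 1$) over the derivation-cohort scores.
6. **Validation**: ROC and confusion metrics on the held-out cohort at that
   cutoff.

### Numerical choices

`fit_logistic_ml()` is a plain Newton (IRLS) iteration with a fixed
contract: convergence when the score norm drops below $10^{-8}$ or the
relative log-likelihood change below $10^{-10}$, at most 100 iterations;
standard errors from the inverse observed information. Divergence is
detected by a coefficient-magnitude guard at $|\beta| > 15$: on the logit
scale 15 is already an odds ratio of $3\times10^6$, far outside anything
estimable from cohort-sized data, so crossing it is treated as complete or
quasi-complete separation and raised as an error. The guard necessarily also
fires on *near*-separated data whose MLE is finite but enormous; for this
package's purposes (screening tables) that is the correct behavior.

ROC curves sweep every distinct observed score as a $\ge$ threshold and
integrate by trapezoid; this is algebraically identical to the Mann–Whitney
statistic $P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)$, which the test-suite
verifies by brute force to $10^{-12}$. Youden ties are broken towards the
larger cutoff (higher specificity — the conservative triage choice, sending
fewer patients to CTE); a $10^{-12}$ tolerance band defines a "tie" so that
floating-point noise in cumulative sums cannot flip the break.

## The decision model

`evaluate_strategy()` computes expected outcomes for a deterministic
decision tree over a cohort (default 100 patients) in which each patient
carries exactly one lesion: 50% angiodysplasia, 30% ulcer/inflammation, 20%
tumor. Base-case test performance (per-lesion sensitivity/specificity of
VCE and CTE), triage performance 73.5%/79.0% and unit costs (USD 1247/518,
THB 42,000/15,400 per VCE/CTE) live in `cea_parameters()`.

Conventions, chosen so that the engine reproduces the robust cells of the
published outcome table and kept identical in the Monte-Carlo simulator:

- **One lesion per patient**; a test detects the patient's own lesion with
  the lesion-specific sensitivity.
- **Tumor staging**: every tumor call on a VCE triggers a follow-up CTE;
  calls arise from true tumor detections and, in non-tumor patients, from
  false calls at rate $1 - \text{VCE tumor specificity}$, independent of
  own-lesion detection. (This reproduces the 19 staging CTEs of the
  capsule-first strategy: $20 \cdot 0.55 + 80 \cdot 0.10$.) Staging CTEs do
  not rescue missed lesions.
- **Triage performance fed to the model is the derivation-cohort operating
  point (73.5%/79.0%)**, not the validation one: only the former reproduces
  the published triage-strategy missed counts (12/50, 8/30, 4/20).
- **Crossover asymmetry**: after a negative CTE the crossover pool is the
  expected misses multiplied by CTE specificity (0.99) — patients with a
  false tumor call are worked up as positives and never cross over
  (reproducing the 62 crossover VCEs of the CTE-first sequential strategy) —
  whereas after a negative VCE *all* missed patients cross over, with
  staging CTEs counted additively on top (reproducing the 37 CTEs of the
  capsule-first sequential strategy). The asymmetry is reverse-engineered
  from the published table rather than derivable from first principles, and
  is flagged as such.
- **Test counts are administrations and add up**: a patient can incur both a
  crossover CTE and a staging CTE. The published *costs* of the sequential
  strategies appear instead to be based on the union (each patient counted
  once, ≈36.55 rather than 37.5 CTEs in the capsule-first sequential arm),
  which is why this package computes \$1441 where the publication prints
  \$1436. The additive convention is kept because it is the one stated for
  the test-count cells; cost cells other than the capsule-first strategy's
  are treated as non-reproducible context.
- **Reported integers round half-down** (4.5 → 4, 37.5 → 37 — both match
  published cells), with a $10^{-9}$ absolute tolerance absorbing binary
  floating-point noise around exact halves; exact expected values are always
  reported alongside.
- In `MURAL-2`, crossover VCE exams in the CTE-first arm do not generate
  further staging CTEs (staging arises from the VCE arm's primary capsule
  exams only); the alternative reading would add ≈2 CTEs per 100 patients.
- The published triage-strategy CTE count (44) is not derivable from first
  principles (we compute ≈40.7). `compat_mural1_followup = TRUE` replicates
  the apparent shortcut — applying the capsule-first strategy's 19% per-VCE
  follow-up rate to the triage strategy's VCE arm (≈44.5) — but the default
  stays first-principles.

`one_way_sensitivity()` re-evaluates all strategies at each endpoint of the
published plausible range of each test-performance parameter, others held at
base case, and returns a tidy long table.

## Synthetic data and what a green test establishes

No patient-level data are available, so `generate_cohort()` emulates the
published cohort structure in two modes:

- **Group-conditional**: draw the mural label at prevalence 34/196, then
  covariates per group — Normal age (57.7 ± 13.0 mural / 65.3 ± 15.4
  non-mural), Normal albumin (3.87 ± 0.71 / 3.35 ± 0.74), Normal hemoglobin,
  and the per-group Bernoulli rates of the thirteen binary covariates.
- **Mechanism**: draw covariates from pooled marginals (age 66.5 ± 15.0,
  albumin 3.41 ± 0.74, pooled flag rates), then the label as
  Bernoulli(logistic probability) under known coefficients (default: the
  published model). Because truth is known, the derivation pipeline can be
  scored on coefficient recovery.

Ages are truncated to [18, 100] years and albumin to [1, 6] g/dL by
rejection sampling — unbounded Normals produce impossible patients — so the
generator's exact targets are truncated-Normal means (for the mural group's
age the shift is < 0.03 years). Binary covariates are sampled independently
within group because only marginal per-group rates are published; real
comorbidities are correlated (CKD with atherosclerosis, age with both), so
synthetic cohorts are somewhat *easier* for model fitting than real ones. A
green parameter-recovery test therefore establishes that the pipeline is a
correct maximum-likelihood machine on data of the stated shape — not that
the published model would replicate on new patients. Hold-out AUROC or
sensitivity/specificity of the original study are likewise not reproducible
without the original cohort and are not asserted anywhere.

On recovery precision: with $n = 5000$ mechanism-mode patients the pipeline
fits on the 70% derivation subset, where the binary coefficients' sampling
SEs are ≈0.12–0.15 and the intercept's ≈0.26. Mean absolute coefficient
error across seeds is the meaningful recovery statistic (asserted < 0.15 in
the acceptance suite); a per-seed, per-coefficient ±0.15 bound is not
attainable at that $n$ and is not asserted.

`simulate_diagnostic_cohort()` simulates the decision tree patient by
patient with the same conventions as the analytic engine; the two are
mutual oracles, and the acceptance suite checks agreement at $n = 10^6$
within three binomial standard errors for all six strategies.

## Known limitations

- No covariate correlation structure, missing-data mechanism, or
  measurement error in the synthetic cohorts.
- The decision model covers diagnostic processes only: no treatment costs,
  QALYs, discounting or probabilistic sensitivity analysis, and the lesion
  universe excludes Meckel's diverticulum and non-small-bowel sources.
- Wald inference only; no profile likelihood, penalization, bootstrap
  optimism correction or recalibration.
- Currencies are independent inputs; no exchange-rate conversion is ever
  performed.
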