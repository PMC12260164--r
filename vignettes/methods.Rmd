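---
title: "Estimating drug treatment effects from code sequences: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating drug treatment effects from code sequences: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Routine health records hold, for every patient, a sparse time-stamped
stream of medical codes: community dispensing records coded with British
National Formulary (BNF) codes and hospital admissions coded with ICD-10.
`txlearner` asks a causal question of such data: *what is the effect of
exposure to a drug class on the probability of a binary outcome within a
180-day follow-up window?* The motivating application is antihypertensive
exposure (ACE inhibitors, beta blockers, calcium channel blockers,
thiazides, statins — identified by their BNF prefixes) and incident
SARS-CoV-2 infection over two pandemic waves, but nothing in the package
is specific to that outcome beyond the default window dates.

Because treatment is not randomised, exposed and unexposed patients
differ systematically (age, deprivation, comorbidity), and the outcome is
rare (~9.5% over 180 days). The package combines three ingredients:

1. a **transformer sequence classifier** as the outcome-risk model,
   consuming the raw lookback code stream plus static covariates;
2. the **X-learner meta-algorithm** for heterogeneous treatment-effect
   estimation around any such risk model;
3. a **synthetic cohort simulator** with known ground truth, because the
   real linked records sit in a trusted research environment and cannot
   be redistributed. Every stage of the pipeline is testable offline
   against the simulator's recorded true propensities and true effects.

# Cohort construction

Raw inputs are three tables (`events.csv`, `demographics.csv`,
`outcomes.csv`); the same schema serves the simulator's output and real
extracts. `buildCohort()` applies, in order:

* **Eligibility** — age ≥ 40 at the index date, non-missing sex, age and
  SIMD decile; an exclusion log counts each reason.
* **Exposure** — a patient is exposed to a drug class in a wave iff at
  least one BNF dispensing record whose code starts with a class prefix
  falls in that wave's lookback window. All windows are half-open
  `[start, end)` at day resolution so boundary days are never counted
  twice; wave 1's lookback is 2019-10-01 to 2020-04-01 and wave 2's is
  2020-04-01 to 2020-10-01.
* **Outcome** — the composite endpoint is the earliest of first positive
  test, first related hospitalisation, and related death, assessed over
  `followupDays` (180) days from the wave's follow-up start; absent
  events are administratively censored at day 180. An outcome date
  before follow-up start marks a prevalent case, which is excluded from
  that wave with a log entry (the source description is silent here;
  exclusion-with-log keeps the incident-outcome definition clean).
* **Undersampling** — wave-1 outcome-negative patients are retained
  independently with probability `ratio = wave-1 cases / wave-2 cases`
  within (age band, sex, SIMD decile) strata; excluded negatives form
  the independent wave-2 analysis pool and are re-labelled on the wave-2
  windows. Age strata are 10-year bands (40–49 … 90+), a concrete choice
  where the source says only "stratified by age, sex and SIMD". Every
  eligible patient therefore lands in exactly one wave.

The calendar windows span 183 days although the design describes a
"180-day" lookback; the package follows the calendar dates and treats
180 as the follow-up length, with day offsets computed as true
differences from the lookback start.

# Sequence encoding

Codes are truncated before tokenisation — BNF to 7 characters (the
chemical-substance stem) and ICD-10 to 3 (the category). Truncation
levels are configurable; these defaults balance vocabulary size against
clinical specificity. The vocabulary is built **only from training
data** (per fold during cross-validation), with ids assigned by
descending count and lexicographic tie-break so builds are reproducible;
unseen or rare codes map to UNK.

Each patient becomes: the `maxLen` most recent lookback events (recency
is the clinically meaningful end of a lookback window), sorted by date
with BNF before ICD-10 on ties; integer day offsets from the lookback
start; and a static vector (age standardised on training statistics,
male indicator, SIMD decile as an integer, diabetes flag). Patients with
no events are legitimate inputs (most patients have no admission): they
get an all-PAD sequence and are scored from statics alone.

**Leakage guard.** When a drug's causal models are fitted, every event
whose raw code starts with that drug's prefixes is removed before
encoding. Otherwise the treatment indicator would be trivially readable
from the input and the counterfactual surfaces would collapse onto the
factual arms. Whether the original study did this is unknowable from its
text; without the guard the method is circular, so the package always
applies it.

# The transformer risk model

The architecture (implemented in compiled code with hand-derived
backpropagation, single-threaded and fully seeded):

* token embedding + learned positional embedding + learned embedding of
  the day offset bucketed into 10-day bins (18–19 buckets per window);
* a stack of post-norm encoder layers: multi-head self-attention,
  residual + layer norm, position-wise feed-forward (ReLU), residual +
  layer norm; padding is handled by processing each sequence at its true
  length, which makes padding invariance exact rather than approximate;
* masked mean pooling over event positions, concatenation of the static
  vector, a two-layer ReLU head, and a logistic output;
* Adam on binary cross-entropy, gradient-norm clipping at 5, dropout
  after attention, after the feed-forward block and in the head; early
  stopping on a stratified validation split (fraction 0.1, patience 3).

Defaults (`transformerConfig()`): embedding 64, 4 heads, 2 layers,
feed-forward 128, dropout 0.1, `maxLen` 256, learning rate 1e-3, at most
30 epochs. The published study's exact hyperparameters live in an
unavailable supplement; these values are sized for cohorts of
10⁴–10⁵ patients on a single CPU. The recovery scenarios in the test
suite and acceptance script use a compact variant
(`scenarioTransformerConfig()`: embedding 32, feed-forward 64, 32-event
sequences, 10 epochs) — a problem-size choice for the simulated cohorts,
stated here as the package's own sizing.

Baselines satisfy the same `predictRisk()` contract: logistic regression
and gradient-boosted trees on bag-of-token counts plus statics, and an
LSTM over the same embedded sequences (last-hidden-state readout,
identical head). The backward passes of both neural models are verified
against central finite differences in the test suite.

# The X-learner

For one drug class with exposure indicator `T` and outcome `Y`:

1. **Outcome surfaces.** `mu1` is fitted on the treated arm, `mu0` on
   the controls (disjoint subsets), each predicting `P(Y = 1 | x)`.
2. **Imputed effects.** For treated patients
   `D1_i = Y_i − mu0(x_i)`; for controls `D0_j = mu1(x_j) − Y_j`.
   Both are clipped to `[−1, 1]`.
3. **Effect surfaces and combination.** `tau1` regresses `D1` on
   covariate summaries over the treated, `tau0` regresses `D0` over the
   controls; a propensity model `g(x)` (logistic regression on statics
   plus `log1p` token counts per code system, clipped to
   `[0.01, 0.99]`) combines them:
   `tau_hat(x) = g(x)·tau0(x) + (1−g(x))·tau1(x)`, clipped to `[−1, 1]`.

The ITE is `tau_hat(x)` — a risk difference — and the ATE is its
arithmetic mean over the evaluation population (the propensity weighting
already lives inside `tau_hat`, so uniform averaging *is* the weighted
estimator). Dispersion is reported as the SD of the `tau_hat`
distribution, plus median and IQR; the "±" the study prints beside ATEs
is not defined in its text, and the SD of the ITE distribution is the
interpretation adopted here.

Design choices worth stating:

* **Stage-3 regressors** default to strongly regularised boosted trees
  (depth 2, learning rate 0.05, 200 rounds, minimum child weight 10% of
  the training rows with a floor of 20). The imputed effects carry
  Bernoulli-scale noise an order of magnitude larger than any plausible
  effect signal; with the looser settings common for pure prediction the
  effect surfaces chase that noise. On the simulator's heterogeneous
  scenario, tightening the regulariser roughly halved the error against
  the true effect surface (PEHE) and substantially raised the rank
  correlation with the true effects, at every seed tried.
* **Seed ensembling** (`ensembleSize`): stochastic training (shuffling,
  dropout, initialisation) injects seed-to-seed variance into `mu0`/`mu1`
  and hence into the imputed effects. Averaging a small number of
  independently seeded fits per surface — two in the canonical scenarios
  — stabilises recovery at roughly double the training cost. The default
  remains 1 (the plain algorithm).
* **Per-drug independence.** The control group for drug `d` is "not
  exposed to `d`" regardless of other drug use, matching the drug-by-drug
  exposure definition; co-medication enters through the input sequences.
* **No cross-fitting** by default, mirroring the described procedure;
  the sub-model seeds are all derived from one master seed.

# The simulator and what passing means

`simulateCohort()` generates: age from a truncated normal (mean 62,
SD 13, range 40–95), sex 56.2% female, a deprivation-heavy SIMD decile
distribution, diabetes 8.1%; a Poisson number (`baseEventRate`, default
12) of background code events per lookback window with codes drawn from
a configurable vocabulary in which admission codes are rare (~85% of
patients have no admission); extra glucose-lowering dispenses for
diabetic patients so diabetes is visible in the sequence; per-drug
exposure drawn from a logistic propensity in age, sex, SIMD, diabetes
and admission count, scaled by `confoundingStrength`, and materialised
as 1+Poisson(1.2) dispensing events of the drug's BNF prefix per window
(so the cohort builder exercises its real exposure path); and the
outcome drawn Bernoulli with probability
`clip(base_risk(x) + Σ_d T_d·tau_d(x), 0, 1)` within each wave's
follow-up, with event dates uniform in the window.

The additive-risk outcome model matches how the effects are reported
(risk differences); configurations whose pre-clipping probabilities
leave `[0, 1]` are rejected as mis-specified rather than silently
clipped. Intercepts are centred analytically (using the known covariate
distributions), not calibrated on the data, so the realised prevalence
matches the target without tuning. One master seed drives everything,
with per-patient streams derived by counter splitting: growing
`nPatients` leaves earlier patients byte-identical.

Ground truth records, per patient and drug, the true propensity, the
true arm-specific outcome probabilities on the analysis window and their
difference (the true ITE). With two waves the analysis window for ground
truth is wave 2 (where most cases occur); the canonical recovery
scenarios use a single wave so the constant-effect ground truth is exact
and free of clipping.

The three frozen scenarios (`scenarioConfig()`):

* **null** — two drugs, zero effect, confounded assignment
  (`confoundingStrength = 1`), prevalence 9.5%. The naive exposed-vs-
  unexposed risk difference is biased (~+1% for the ACEI-like drug); the
  X-learner estimate should sit within ±0.03 of zero.
* **constant** — one drug, `tau* = −0.10`, base prevalence raised to
  0.30 so `base + tau` never leaves `[0, 1]`; the ATE should land within
  ±0.03 of −0.10.
* **heterogeneous** — `tau*(age) = −0.05 − 0.003·(age − 60)`: a
  clinically plausible spread (≈ +0.01 at age 40 to −0.155 at 95). The
  Spearman correlation between estimated and true ITEs should exceed
  0.5.

What passing these does **not** show: the simulator reproduces only the
marginal structure of real dispensing data (rates, prevalences,
confounding direction). It has no inter-patient transmission, no
vaccination era, no code co-occurrence structure beyond the diabetes
marker, and its outcome model is exactly the additive form the estimator
assumes. Recovery here demonstrates correctness of the machinery, not
performance on NHS data; the study's real-data metrics and effect
estimates are not reproducible without the original linked NHS extract
inside its trusted research environment and are
deliberately out of scope.

# Evaluation machinery

* **Cross-validation** (`crossValidate()`): stratified-by-outcome folds
  (re-drawn on the rare single-class fold, error after 5 attempts);
  vocabulary and age scaler rebuilt per training fold; accuracy and F1
  at a fixed 0.5 threshold (configurable); AUPRC by trapezoidal
  integration over the PR points at every distinct score threshold,
  anchored at recall 0 with the first threshold's precision — under
  which a constant score scores exactly the prevalence, the no-skill
  baseline. On ~9.5%-prevalence synthetic cohorts the transformer's
  cross-validated AUPRC sits modestly above that baseline and F1 at the
  0.5 threshold can be 0 (the model rarely crosses 0.5); this reflects
  the simulator's deliberately weak signal, not the evaluation code.
* **Paired comparisons** (`pairedIteComparison()`): Wilcoxon signed-rank
  on paired ITEs — zeros dropped, mid-ranks for ties, tie-corrected
  normal approximation with continuity correction (exact distribution
  when there are no ties among ≤ 25 non-zero pairs); effect size
  `r = |Z|/√n` over non-zero pairs, banded Negligible/Small/Moderate/
  Large at 0.1/0.3/0.5 (closed on the left); Cohen's d with the
  asymptotic-variance CI. No multiplicity adjustment is applied, and
  results are reported per comparison.
* **Recovery** (`recoveryReport()`): bias, RMSE/PEHE (the same
  root-mean-square quantity under its two common names) and Spearman
  correlation against the simulator's truth.

# Numerical choices and degenerate inputs

Layer-norm epsilon 1e-5; propensity clipping 0.01; ITE clipping to
`[−1, 1]`; Adam (0.9, 0.999, 1e-8) with global gradient clipping at 5;
BCE log-clamping at 1e-12; empty sequences pool to a zero vector; an
empty vocabulary encodes everything as UNK; single-class training labels
and undersized arms abort with diagnostics rather than returning
degenerate fits; NaN training loss aborts. Same-day events tie-break BNF
before ICD-10, then code lexicographically. All CSV artifacts are
written deterministically and each pipeline stage records a manifest
with config hash, seed and file checksums, so reruns are byte-identical.

# Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` run the recovery scenarios at
n = 20,000 patients with the compact transformer, prevalence checks at
n = 50,000 (simulation only), cross-validated metrics at n = 6,000 with
5 folds, the sign-recovery property at 20 replicates of n = 2,000 with
the logistic base learner, and the exact-algebra and metric oracles at
n ≤ 20. These sizes are the package's validation conditions; larger
cohorts only improve the estimates.

# Known limitations

* The transformer is desk-scale; no pre-trained clinical embeddings, no
  GPU path, no hyperparameter search beyond the config surface.
* The simulator's independence assumptions (codes i.i.d. given rates,
  no temporal clustering) make its sequences easier than real ones; the
  time-embedding pathway is exercised but not stressed.
* Residual confounding by unmeasured variables is, as always,
  untestable; the null-recovery scenario only certifies behaviour under
  the simulator's measured-confounding model.
* With two simulated waves the constant-effect ground truth refers to
  the per-wave 180-day risk difference; the two-wave composite risk
  difference is larger in magnitude and is not the estimand.
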