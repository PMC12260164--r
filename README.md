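# txlearner

Individual and average treatment effects of drug exposures on a 180-day
binary infection outcome, estimated from longitudinal prescription and
admission code sequences with a transformer-based X-learner.

## What problem this solves, and for whom

Pharmacoepidemiologists often have nothing richer than routinely
collected administrative streams: community dispensing records (BNF
codes), hospital admissions (ICD-10), demographics. `txlearner` turns
those streams into causal effect estimates for drug classes — here
antihypertensives (ACE inhibitors `0205051`, beta blockers `0204000`,
calcium channel blockers `0206020`, thiazides `0202010`, statins
`0212000B0/C0/X0/Y0`) against incident SARS-CoV-2 infection across two
pandemic waves — while adjusting for the confounding visible in the
code history itself.

The core estimator is the **X-learner** with a **transformer sequence
classifier** as base model. For drug exposure `T` and outcome `Y` with
covariates `x`:

1. outcome surfaces `μ₁(x) = P(Y=1 | x, T=1)` and `μ₀(x)` are fitted on
   the two arms (transformer over the tokenized 180-day code stream,
   fused with age, sex, SIMD decile and diabetes status);
2. counterfactual imputations `D¹ᵢ = Yᵢ − μ₀(xᵢ)` (treated) and
   `D⁰ⱼ = μ₁(xⱼ) − Yⱼ` (controls);
3. effect surfaces `τ₁`, `τ₀` regress the imputations on covariates,
   and a propensity score `g(x)` combines them:

   τ̂(x) = g(x)·τ₀(x) + (1 − g(x))·τ₁(x)

The ITE τ̂(x) is a risk difference in [−1, 1]; the ATE is its mean over
the evaluation population. Because the real NHS cohort cannot be
redistributed, the package ships a synthetic-cohort simulator with known
ground truth (true propensities, true ITEs), so the whole pipeline —
eligibility, BNF-prefix exposure, composite outcomes, wave splitting,
stratified undersampling, encoding, training, meta-learning, evaluation
— is testable end to end. The transformer and the LSTM baseline are
implemented in compiled code (RcppArmadillo) with hand-derived,
finite-difference-verified backpropagation; no deep-learning framework
is required.

## Worked example

A single-wave synthetic cohort of 4,000 patients in which the
ACEI-class drug truly *reduces* 180-day risk by 10 percentage points
(`scenarioConfig("constant")`), analysed with the compact transformer:

```r
library(txlearner)

cfg    <- scenarioConfig("constant", nPatients = 4000, seed = 42)
sim    <- simulateCohort(cfg)
cohort <- buildCohort(cohortEvents(sim), cohortDemographics(sim),
                      cohortOutcomes(sim), waves = defaultWaves()[1])

fit <- fitXLearner(cohort, "ACEI",
                   cohortEvents(sim), cohortDemographics(sim),
                   baseLearner = "transformer",
                   baseConfig  = scenarioTransformerConfig(1),
                   maxLen = 32, ensembleSize = 2, seed = 7)

lb  <- cohortLabels(cohort)
ite <- estimateIte(fit, lb$patient_id,
                   cohortEvents(sim), cohortDemographics(sim))
print(estimateAte(ite), digits = 3)
rec <- recoveryReport(ite, groundTruth(sim))
cat(sprintf("bias %.3f, PEHE %.3f\n", rec$bias, rec$pehe))
```

```
  drug     ate     sd  median iqr_low iqr_high    n
1 ACEI -0.0736 0.0533 -0.0775  -0.114  -0.0418 4000
bias 0.026, PEHE 0.059
```

Reading it: the estimated ATE of −0.074 says exposure lowers 180-day
infection risk by about 7.4 percentage points in this cohort, against a
simulated truth of exactly −0.10 — a bias of +0.026 at this modest
cohort size (at the canonical n = 20,000 the same pipeline lands within
±0.01 of the truth; see the acceptance script below). `sd`, `median`
and the IQR describe the spread of per-patient effects τ̂(x), and PEHE
is the root-mean-square error of those per-patient estimates against
the true ITEs — a quantity only a simulator can provide.

Downstream analyses mirror the study machinery: `crossValidate()` for
accuracy/F1/AUPRC of the risk models under 5-fold cross-validation,
`pairedIteComparison()` for Wilcoxon signed-rank contrasts of paired
ITEs between drug classes (effect size r banded
Small/Moderate/Large at 0.1/0.3/0.5, Cohen's d with CI),
`subgroupIteSummaries()` for ITE consistency across age, sex and
deprivation.

A file-based pipeline with the same functionality (subcommands
`simulate`, `build-cohort`, `train`, `causal`, `evaluate`, `compare`,
`report`; YAML config; manifests with checksums) is available through
`runPipeline()` or the thin CLI at `inst/scripts/txlearner.R`.

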