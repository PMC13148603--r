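---
title: "Auditing diagnostic equity of a urine-culture prediction model"
author: "utiaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing diagnostic equity of a urine-culture prediction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utiaudit)
```

## The problem

Urinary tract infection (UTI) is among the most common emergency-department
(ED) presentations, and it is routinely both over- and underdiagnosed: the
laboratory gold standard — the urine culture — does not result within an ED
visit, so clinicians act on urinalysis results and clinical impression. A
classifier that predicts culture positivity from the urinalysis alone could
standardize this decision, but a model deployed across a diverse population
must be examined for how its errors distribute across demographic groups,
not just on average.

`utiaudit` implements that examination end to end on synthetic data with
known ground truth:

1. **simulate** an ED encounter cohort (demographics, urinalysis, culture,
   symptoms, physician actions) with configurable generative parameters;
2. **harmonize** heterogeneous urinalysis reporting dialects onto one
   ordinal scale per component;
3. **label** each encounter: culture positivity, strict/liberal UTI, and a
   rule-based proxy for physician diagnosis;
4. **train** a gradient-boosted classifier of culture positivity on the
   urinalysis panel plus clinical site;
5. **audit** model versus physician over- and underdiagnosis across
   intersectional demographic groups.

Because no row-level clinical data ship with the package, every stage is
validated against the synthetic generator's latent truth and against
brute-force oracles on small fixtures.

## Outcome definitions

A urine culture is **positive** when it grew at least 10,000 CFU/mL of a
pathogenic organism; growth of skin or genital flora, and sub-threshold
growth, are negative. Two UTI definitions are carried through every
analysis:

* **strict** (primary): positive culture AND at least one UTI sign or
  symptom. The symptom requirement separates true UTI from asymptomatic
  bacteriuria, which typically does not warrant treatment.
* **liberal** (sensitivity): positive culture alone.

Strict implies liberal by construction, and the package asserts this
containment on every cohort.

**Physician diagnosis** is a composite rule, because visit coding is
incomplete: an encounter counts as physician-diagnosed if it carries an
explicit UTI code (cystitis, pyelonephritis, unspecified UTI or a synonym),
or else a UTI-relevant antibiotic *and* a nonspecific UTI-attributable
diagnosis *and* no alternative infectious diagnosis that would explain the
antibiotic. Adding an alternative diagnosis can only revoke an inferred
diagnosis, never create one — a monotonicity the tests exercise. The
organism, diagnosis and antibiotic lists ship as an overridable JSON
resource (`inst/extdata/code_lists.json`); they are documented stand-ins
assembled from standard uropathogen and first-line-therapy lists, since
site-specific lists are institution-internal.

## Urinalysis harmonization

Sites report dipstick and microscopy components on different scales. The
harmonizer maps three dialects — qualitative (`negative/trace/moderate/
large`), semiquantitative (`1+`..`4+`), quantitative (numbers with units) —
onto a unified ordinal scale per component: four levels for dipstick
chemistries, four binned levels for microscopy counts (none, 0–10, 11–50,
>50 per high-power field). Nitrite is kept **binary** (negative/positive):
clinical assays report it qualitatively, and for a tree-based classifier
any monotone recoding of a single feature is decision-equivalent, so a
two-level scale is used rather than embedding the positive level inside a
four-level scale; this also keeps every dialect map surjective onto
consecutive levels, which the loader validates.

Two deliberate policies:

* **missingness passes through; unknown vocabulary fails loudly.** Only
  true missingness may reach the model (which handles it natively, without
  imputation); a raw string outside the declared vocabulary raises an error
  naming the component, dialect and value rather than being coerced to
  missing.
* **rendering is the exact inverse of harmonization.** The generator emits
  raw strings with `render_raw_urinalysis()`, and
  `harmonize_component(render_raw_urinalysis(x))` is the identity for every
  component, dialect and level — a property tested exhaustively.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which everything downstream is validated. Where a published multisite ED
cohort states a quantity, the default reproduces it; everything else was
chosen once as a realistic value and frozen.

| parameter | default | origin |
|---|---|---|
| culture positivity | 0.151 | reported cohort prevalence |
| P(any symptom \| positive) | 0.892 | reported symptomatic fraction |
| P(any symptom \| negative) | 0.863 | reported rate in the no-UTI group |
| physician sensitivity / FPR | 0.634 / 0.091 | reported FNR 36.6%, FPR 9.1% |
| explicit-code share of diagnoses | 0.92 | reported 92% explicit |
| per-component missingness | 0.02 | "low missingness", rate unstated |
| encounters per patient | 1.25 (n_patients = 0.8 n) | unstated; modest revisit rate |
| latent intensity separation | N(1.5, 0.8) vs N(−0.85, 0.9) | unstated; see below |

**Biology.** Each encounter draws a latent culture state at the configured
prevalence, then a latent *infection intensity*. Every urinalysis component
is a noisy monotone readout: `x = signal * intensity + N(0,1)`, cut at
fixed thresholds into ordinal levels. Signal strengths default to a
microbiologically sensible ordering (bacteria 1.1, white blood cells 1.0,
leukocyte esterase 0.95, nitrites 0.85, blood/protein weak, glucose/ketones
near zero, epithelial cells −0.25 as a contamination marker), and nitrite's
single high cutpoint makes it specific but insensitive — the classic
dipstick behavior. The intensity separation was calibrated once, by
simulation, so that the default cohort supports a classifier in the
low-0.93 AUROC range — the performance regime reported for real urinalysis
data — and then frozen. Setting all signals to zero yields a null cohort on
which the classifier must score at chance; the tests assert both regimes.

**Culture records encode the latent state exactly**: positives grow a
uropathogen at ≥10,000 CFU/mL; negatives split 70/20/10 between no growth,
non-pathogenic growth and sub-threshold pathogen growth. The labeling module
must therefore recover the latent state perfectly, which is asserted.

**Physician behavior** acts on the latent strict-UTI state with
group-specific sensitivity and false-positive rate (a wildcard-matched
table; the default single row is the reported overall operating point).
Decisions are then *encoded* as either an explicit UTI code (92%) or an
antibiotic plus nonspecific diagnosis; non-diagnosed encounters sometimes
receive an antibiotic explained by an alternative diagnosis, exercising the
blocked branch of the proxy rule. Injected group-specific error rates must
be recovered by the audit within three Monte-Carlo standard errors — the
package's core self-consistency check.

**Demographics.** The default mix crosses four age bins x sex x seven race
x three ethnicity categories with weights built from realistic ED marginals
(71% female, age skewed young with a long older tail, race conditioned on
ethnicity). At full study scale roughly eighteen to nineteen cells clear a
2000-encounter floor, mirroring the published cohort's nineteen; the
boundary cells intentionally hover near the cutoff. Demo runs scale the
floor proportionally (2000/149,449 of the cohort).

**Determinism.** One master seed fans out to fixed per-stream seeds
(demographics, biology, urinalysis, symptoms, physician), so perturbing one
stream leaves the others unchanged, and the same config + seed reproduces a
byte-identical table.

What the generator does **not** emulate: free-text notes (symptom flags are
already binary), site-specific assay biases beyond the reporting dialect,
correlated missingness, antibiotic pharmacology, pregnancy and disposition
pathways, and demographic differences in disease prevalence (group
differences enter only through physician behavior unless configured
otherwise). Passing tests therefore demonstrate internal correctness of the
pipeline's logic and estimators, not performance on real patients.

## The classifier

An XGBoost binary classifier predicts culture positivity from exactly ten
features: the nine harmonized ordinal components (integers, `NA` passed
natively to the tree splitter — no imputation) and the clinical site
(one-hot, included to absorb site-specific reporting variance). Demographic
variables never enter the matrix; a guard raises if they do, and a test
asserts the exact feature set — excluding demographics from the predictors
is the design's primary bias-avoidance choice.

Protocol: 80/20 train/test split stratified *by patient* (all encounters of
a patient land on one side; patient-level outcome used as the stratum);
per-observation class weights equal to the negative:positive ratio;
hyperparameters tuned by seeded random search over depth 2–10, learning
rate 0.01–0.3 (log), 100–1000 trees, subsampling 0.5–1, L1/L2 0–5,
scored by mean patient-grouped 5-fold cross-validated AUROC. Trials are
drawn one at a time from a seeded stream, so a budget of 50 evaluates a
superset of a budget of 5 and the attained objective is monotone in the
budget — a property the tests check. A budget of 0 fits documented
defaults and flags it. After tuning, the chosen configuration is refit on
the full training set for held-out evaluation, and cohort-wide
probabilities for the audit come from 5-fold *cross-fitting*: every
encounter is scored by a model that never saw it or its patient.

Attribution uses the booster's tree-path additive contributions (SHAP
values): per row they sum, with the base value, to the model's log-odds
output, verified numerically; site indicators are aggregated into one
`site` feature. On default cohorts the ranking recovers the generating
signal (bacteria, white blood cells, leukocyte esterase on top; elevated
nitrite strongly positive).

## The equity audit

Encounters are crossed into age-bin x sex x race x ethnicity cells;
cells below `min_group_size` (default 2000 encounters) are excluded from
per-group analyses but always counted in overall metrics. Per group and
overall, at a decision threshold:

* **overdiagnosis** = FP / (FP + TN) (false-positive rate),
* **underdiagnosis** = FN / (TP + FN) (false-negative rate),
* **accuracy**, and the **diagnostic odds ratio**
  DOR = (TP/FN) / (FP/TN), with the Haldane–Anscombe +0.5 correction (and a
  flag) when any cell is zero.

Three thresholds are reported:

* **policy-constrained** (primary): scanning integer percents downward from
  99, the highest threshold at which the model's underdiagnosis rate is
  *strictly below* the physician's in every audited group, computed against
  the strict definition — the operating point at which no audited group
  would see more missed diagnoses if the model replaced clinical judgment.
  The downward scan starts at 99 rather than some interior point; since
  feasibility is monotone in the threshold, the result is invariant to the
  starting point as long as the scan covers it. "Strictly below" is chosen
  over "at or below" so the claim of no increase in missed diagnoses holds
  with margin. If even the lowest candidate fails, the selector raises an
  explicit infeasibility error listing the violating groups — a model that
  is not better than the physician cannot be given a compliant threshold,
  and silently returning one would be misleading.
* **fixed external** 42.3%, a published estimate of the probability at
  which half of primary-care clinicians would treat; applied exactly, never
  rounded to the integer grid.
* **Youden-optimal**: argmax of J = TPR − FPR over the integer grid, ties
  broken toward the *lowest* threshold (favoring sensitivity), with the
  tie-break recorded in the output.

Under the strict definition the model's decision is
`probability >= threshold AND any sign/symptom` — the symptom requirement
applied as a binary rule; under the liberal definition the threshold alone.
Physician metrics always use the same truth labels as model metrics.

**Cross-group variance** is summarized by the coefficient of variation
(sample SD over mean) of accuracy and DOR across audited groups, for the
model and the physician separately. Its 95% CI uses a normal approximation
with constant half-width `z * sqrt(1/(2(n−1)))` and the lower bound floored
at zero; with n = 19 groups the half-width is 1.96/6 ≈ 0.327. This simple
approximation reproduces, to rounding, all four intervals printed in the
published analysis the package mirrors, which is exactly the check in the
test suite; the formula name is recorded in every report so alternative
interval estimators can be registered later.

Finally, the **decile table** ranks encounters into ten equal-count bins of
predicted probability and reports physician diagnosis and observed culture
positivity rates per bin — an indirect estimate of the threshold physicians
implicitly operate at.

## Numerical and degenerate-input policies

* Classification is `probability >= threshold`; already-binary decisions
  bypass the threshold.
* A group with no true positives has undefined underdiagnosis: reported as
  `NA`, never dropped silently; such groups are skipped by the policy
  constraint (they cannot be made worse on misses).
* AUROC uses the exact rank/U-statistic with midrank ties; a single-class
  group's AUROC is `NA` with its row retained.
* PR-AUC is step-interpolated average precision (no linear interpolation,
  which is biased upward).
* CV requires at least two values and a positive mean; DOR an all-nonzero
  or corrected table.
* All randomness flows from explicit seeds; xgboost runs single-threaded
  with its own seed pinned, so pipeline reruns are byte-identical.

## Problem sizes

The package's demo configuration simulates 20,000 encounters (16,000
patients), tunes over 12 trials with 100–400 trees, and audits with the
proportionally scaled group floor (≈268 encounters). The test suite uses
cohorts of 4,000–18,000 rows, tuning budgets of 1–4 and 30–120 trees —
sizes chosen so the full statistical behavior (prevalence bands, error-rate
recovery within Monte-Carlo error, chance-level nulls) is exercised while a
complete run stays fast on a laptop.

## Known limitations

* The latent-intensity model is one-dimensional: all components are
  conditionally dependent only through infection intensity. Real urinalysis
  components have additional correlation structure (e.g. hematuria from
  non-infectious causes).
* Group differences arise only from configured physician behavior and
  sampling noise; biological prevalence differences between groups are not
  modeled by default, so cross-group CVs on default synthetic cohorts are
  smaller than those observed in real data.
* The physician proxy and the simulated physician share their rule
  structure, so proxy misclassification (a real-world concern) is absent by
  construction unless configured.
* The CV interval is a crude normal approximation with width independent of
  the CV's magnitude; it is used because it is the documented convention of
  the analysis this package mirrors, not because it is efficient.
* Harmonization tables and code lists are defaults, not any institution's
  validated lists; both are override points.
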