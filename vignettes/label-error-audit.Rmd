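---
title: "Auditing gold-standard label errors in screening classifier evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing gold-standard label errors in screening classifier evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labelaudit)
```

## The statistical problem

A binary screening classifier is evaluated against human labels on a data
set far too large for expert re-reading. The labels carry errors at some
small rate, but those errors are not spread evenly over the evaluation: a
wrong positive label on an image the classifier (correctly) called negative
lands in the false-negative cell, and a wrong negative label on a
classifier-positive image lands in the false-positive cell. The discrepancy
cells therefore *concentrate* label errors, and apparent sensitivity and
specificity can be badly biased even when overall label quality is high.

The audit implemented here estimates that bias from a feasible amount of
expert work and corrects for it:

1. **Evaluate** the classifier against the raw labels: confusion cells
   `TP, FP, TN, FN` (convention: "positive" always means referable
   disease; FN/FP are defined against the label) and the usual metrics.
   At the participant level, a participant is positive if at least one of
   their gradable images is positive — applied independently to the human
   and the classifier labels.
2. **Sample** each discrepancy stratum uniformly without replacement
   (defaults: 10% of the FN stratum, 5% of the FP stratum, the ceiling of
   the fractional size) and have the sampled units re-read by masked
   experts whose verdict is treated as truth.
3. **Estimate** the stratum label-error rates: `fnr` and `fpr` are the
   proportions of sampled units whose label was overturned (i.e. the
   verdict sided with the classifier), as binomial proportions `k/n` with
   Wald standard error and an exact Clopper–Pearson interval.
4. **Correct**: the expected flips are `pn = fnr · FN` (positive to
   negative) and `np = fpr · FP`; corrected totals are
   `positives' = positives + np − pn`, and the corrected confusion matrix
   is `TP' = TP + np`, `FP' = FP − np`, `TN' = TN + pn`, `FN' = FN − pn`.
   All metrics are recomputed from the corrected cells. The overall
   label-error rate is `(pn + np)/N`.
5. **Propagate and compare**: the corrected quantities are deterministic
   functions of the two sampled rates, so intervals follow from the
   binomial uncertainty of `k` (parametric bootstrap by default, delta
   method as an analytic alternative); pre/post proportions are compared
   by Pearson chi-square, and both operating points are compared with the
   laboratory reference in percentage points ("gap analysis").

### Assumptions

* Adjudication verdicts are correct (the audit replaces one gold standard
  with a better one, not with truth; the oracle's own error rate can be
  emulated in the synthetic module).
* Sampled units are exchangeable with their stratum — guaranteed here by
  uniform seeded sampling.
* Label errors in the *concordant* cells (TP, TN) are not corrected. The
  generalized form `correct_labels(cm, fnr, fpr, tp_error_rate,
  tn_error_rate)` accepts spot-check rates for those cells, but they
  default to 0. The consequences are discussed under *Limitations*.
* The classifier is a fixed input; it is never re-thresholded or retrained.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| FN-stratum sampling fraction | 0.10 | ceiling rule; realized `n` is recorded and used in all downstream math |
| FP-stratum sampling fraction | 0.05 | as above |
| CI method | Clopper–Pearson | exact; Wilson and Wald selectable |
| Confidence level | 0.95 | |
| Score threshold | 0.5 | used only when a score but no binary prediction is supplied |
| Bootstrap replicates | 1000 | percentile intervals |
| Chi-square continuity correction | off | flagged in the report |

Displayed percentages are rounded to one decimal, half away from zero;
internal computation is always full precision. Expected counts (`pn`, `np`,
corrected cells) stay fractional internally and are rounded only for
reporting.

## The synthetic cohort generator

`cohort_params()` / `simulate_cohort()` generate a screening program with
known ground truth so that every stage of the audit is testable offline:

* **Structure.** `n_participants` participants contribute
  `1 + Poisson(2.1)` images each (mean 3.1). A participant carries
  referable disease with probability 0.074; each image of a diseased
  participant is positive with probability 0.84, so image-level prevalence
  is ≈ 6.2% and no positive images occur in disease-free participants
  (participant truth is the OR of image truth). Each image is ungradable
  with probability 0.10, independently.
* **Two-stage grading.** A primary grader labels every gradable image by
  flipping the truth with probability `1 − sensitivity` (positives) or
  `1 − specificity` (negatives). All stage-1 positives plus a random 15%
  of stage-1 negatives are re-read by a second primary; disagreements go
  to an arbiter whose call is final. The closed-form chance of a positive
  final label, used to verify the simulator, is
  `q1·(q2 + (1−q2)·q3) + (1−q1)·r·q2·q3`, with `q_i` the per-rater
  positive-call probabilities and `r` the re-grade fraction.
* **Grader operating points.** Primaries default to sensitivity 0.91 /
  specificity 0.91, the arbiter to 0.98 / 0.998. These were chosen so the
  *final* labels run at ≈ 92% sensitivity with a ≈ 0.9% wrong-positive
  rate — the label quality that large DR-screening adjudication studies
  actually measure, and within the reported range of individual grader
  accuracy. Under these defaults the synthetic FN stratum has a label-error
  rate around 0.65 and the overall label-error rate is ≈ 1.3%, i.e. the
  regime the audit is designed for.
* **Classifier.** Scores are drawn from class-conditional Beta
  distributions — positives `Beta(a, 1)`, negatives `Beta(1, b)` with `a`
  and `b` solved so that thresholding at 0.5 attains the requested
  operating point (default 0.925 / 0.985) exactly in expectation.
  Degenerate operating points (0 or 1) use uniform scores on one side of
  the threshold. Setting `difficulty_sd > 0` adds a per-image normal shift
  on the logit of every rater's and the classifier's error probability,
  inducing correlated errors; it is off by default to keep the error
  process analyzable.
* **Oracle.** `truth_oracle()` returns verdicts equal to the hidden truth,
  or corrupts them through a two-reader-plus-arbiter panel with given
  operating points.

Everything is a pure function of `(params, seed)`; cohorts rewrite
byte-identically.

**What the generator does not emulate:** image content and quality beyond a
Bernoulli ungradable flag; per-grade (5-level) structure — graders emit
binary referable calls directly; systematic per-center or per-device label
biases; clinical reasons for errors; and (by default) correlation between
grader and classifier mistakes on "hard" images. Passing tests on synthetic
cohorts therefore demonstrate the statistical machinery under the audit's
own assumptions, not robustness to correlated or adversarial label noise in
any particular real program.

## Numerical and design choices

* **Clopper–Pearson as default CI.** The exact interval is computed from
  beta quantiles; at the audit's typical stratum sizes (hundreds to a few
  thousand) it is near-indistinguishable from Wilson but never
  anti-conservative, and it reproduces published adjudication intervals to
  the printed decimal where Wald does not. The reported "SD" of a rate is
  the Wald standard error `sqrt(p(1−p)/n)`.
* **Ceiling rule for fractional sample sizes**, and all downstream math
  uses the realized `n`, never the nominal fraction.
* **Order-invariant sampling.** Samples are drawn from the sorted unit
  ids under the given seed, so permuting input rows cannot change a
  manifest.
* **AUROC** is the Mann–Whitney statistic computed from midranks, so ties
  contribute 1/2 exactly.
* **Zero denominators** make a metric `NA` with a warning — never silently
  0 or 1.
* **Chi-square without continuity correction** by default (the correction
  is available and flagged); fractional corrected counts are used as
  given. A 2×2 table with an empty margin is rejected with a pointer to
  exact tests rather than returning a 0/0 statistic.
* **Cells-only mode.** `audit_from_counts()` runs the entire correction
  from eight integers, because the method is identified by the confusion
  cells plus the two adjudicated counts. This is also how a published
  audit can be reproduced without any per-image data, in well under a
  second.
* **Participant-level correction is independent** of image-level
  correction, with its own sampled rates; no cross-level consistency is
  forced (image and participant rates answer different questions).

## Validation problem sizes

The test suite validates the pipeline end to end on simulated programs:
Clopper–Pearson coverage at 2000 simulated binomials per configuration;
AUROC against exhaustive pair enumeration on instances of up to 50 units;
subsample-size stability at 500 replicates per size; and full
audit-plus-correction recovery on 200 independent cohorts of 20,000
participants (~62,000 images) each, checking that the realized stratum
error rates fall inside their 95% CIs and the true positive count inside
the propagated 95% interval in at least 90% of replicates. A single
~200,000-image cohort is additionally spot-checked.

## Limitations

* **Uncorrected concordant cells bias the corrected totals.** Labels that
  are wrong *and* agreed with by the classifier (truth-positive images the
  classifier also missed, in the TN cell; truth-negative images it also
  flagged, in the TP cell) are invisible to the discrepancy audit. The
  resulting shortfall in corrected positives grows linearly with cohort
  size while the propagated interval grows only as its square root, so at
  very large scales the interval will sit systematically below the true
  positive count (in our synthetic world the prevalence-recovery coverage
  falls from ≈ 94% at 62k images to ≈ 87% at 200k). Spot-check rates for
  TP/TN cells can be supplied to `correct_labels()` when such audits
  exist.
* **The corrected metrics treat the extrapolated flips as exact
  reassignments** within the strata; they are expectations, which is why
  fractional cells are retained and uncertainty is propagated rather than
  asserted.
* **Adjudicator error is not modeled in the correction itself** — verdicts
  define truth. The synthetic oracle can be corrupted to study the effect,
  but no identifiable correction for adjudicator error is attempted from
  these data alone.
* The pre/post chi-square comparisons treat the corrected counts as
  observed data; their p-values are descriptive, not tests that account
  for the sampling uncertainty of the correction.
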