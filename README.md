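# labelaudit

Auditing and correcting gold-standard label errors when evaluating a binary
screening classifier on large real-world data sets.

## The problem

In screening programs — the motivating case is fundus-image screening for
referable diabetic retinopathy (DR) — a deployed classifier is evaluated
against human grading outputs that serve as the "gold standard". Those
labels are themselves imperfect, and their errors are concentrated exactly
where the evaluation looks: in the cells where classifier and label
disagree. A classifier that is right while the label is wrong is booked as
a false negative or false positive, so even a ~1% label-error rate can
depress apparent sensitivity by ten points or more and manufacture a
spurious gap between laboratory and real-world performance.

`labelaudit` implements a post hoc audit for this situation. A random
sample of each discrepancy stratum is re-read by masked experts
("adjudication"); the stratum label-error rates are the proportions of
overturned labels,

    fnr = k_FN / n_FN    (FN stratum: classifier negative, label positive)
    fpr = k_FP / n_FP    (FP stratum: classifier positive, label negative)

each with a Wald standard error `sqrt(p(1-p)/n)` and an exact
Clopper–Pearson 95% CI. Extrapolating to the full strata gives the expected
label flips

    pn = fnr × FN    (positive → negative)
    np = fpr × FP    (negative → positive)

corrected label totals `positives' = positives + np − pn` (and symmetrically
for negatives), and a corrected confusion matrix

    TP' = TP + np,  FP' = FP − np,  TN' = TN + pn,  FN' = FN − pn

from which all diagnostic metrics are re-estimated. Uncertainty in the two
sampled rates is propagated to every corrected quantity by parametric
bootstrap (or the delta method), and pre/post operating points are compared
with each other (chi-square) and with the laboratory reference (gap
analysis).

A seeded synthetic-cohort generator (`simulate_cohort()`) emulates the
screening program — participants contributing ~3 images, a two-stage human
grading workflow with per-grader error rates and an arbiter, and a
classifier with a configurable operating point — so the entire pipeline can
be validated end to end against known ground truth.

## Worked example

The audit is fully determined by eight integers: the four confusion cells
and the overturned/sampled counts of the two adjudicated strata. Using the
published values of a nationwide DR-screening evaluation (736,083 images;
560/880 FN-stratum and 140/2710 FP-stratum labels overturned; laboratory
operating point 92.5% sensitivity / 98.5% specificity):

```r
library(labelaudit)
report <- audit_from_counts(
  tp = 36401, fp = 57886, tn = 632457, fn = 9339,
  k_fn = 560, n_fn = 880, k_fp = 140, n_fp = 2710,
  lab_sensitivity = 0.925, lab_specificity = 0.985, seed = 1
)
report
```

```
=== Label-error audit (image level) ===

-- Pre-correction --
Diagnostic metrics (image level)
  accuracy     90.9%
  precision    38.6%
  sensitivity  79.6%
  specificity  91.6%
  f1           52.0%

-- Stratum label-error rates --
fnr: 63.6% (k = 560 / n = 880; SE 1.6%; 95% CI [60.4, 66.8]%, clopper_pearson)
fpr: 5.2% (k = 140 / n = 2710; SE 0.4%; 95% CI [4.4, 6.1]%, clopper_pearson)

-- Correction --
Label correction (image level, N = 736083)
  expected flips: pn = 5943 (pos->neg), np = 2990 (neg->pos), total 8933
  corrected totals: 42787 positive / 693296 negative
  overall label-error rate: 1.2%
Diagnostic metrics (image level)
  accuracy     92.1%
  precision    41.8%
  sensitivity  92.1%
  specificity  92.1%
  f1           57.5%

Lab vs real-world gap (percentage points, lab minus observed)
  sensitivity: 12.9 (pre) -> 0.4 (post)
  specificity: 6.9 (pre) -> 6.4 (post)
```

Reading: against the raw labels the classifier appears to miss one in five
referable images (sensitivity 79.6%). Adjudication shows 63.6% of
FN-stratum labels were themselves wrong; extrapolated, ~8933 of 736k labels
(1.2%) flip, and against corrected labels the classifier operates at 92.1%
sensitivity — within 0.4 points of its laboratory value.

With per-image data instead of printed cells, use `run_evaluate()` (metrics
from a CSV of image records), `draw_audit_samples()` /
`write_sample_manifest()` (hand-off to adjudicators), and `run_audit()`
(full pipeline once verdicts return). `inst/cli/labelaudit.R` wraps these
as `simulate` / `evaluate` / `audit` subcommands.

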