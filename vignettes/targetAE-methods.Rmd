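---
title: "Methods: target-matched adverse-event prediction"
author: "targetAE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-matched adverse-event prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetAE)
```

## The prediction problem

A newly approved ("test") drug has a short safety record; drugs that share
its pharmacological action — agonists or antagonists at one or more of the
same molecular targets — have mature labels and years of literature. The
package predicts, for each of a fixed vocabulary of adverse-event groups,
whether the test drug's label will come to carry the event, using its
comparators' safety evidence. The unit of evidence is the
(comparator, test drug, adverse event) association; the unit of decision is
the (test drug, adverse event) pair.

Adverse events are groups of MedDRA Preferred Terms in which
mechanistically similar, interchangeably reported terms count as one event
(for example "PANCREATITIS" and "PANCREATITIS ACUTE"). The packaged
vocabulary has 167 Preferred Terms in 135 groups; `mapPTsToGroups()`
collapses Preferred-Term presence to group presence by logical OR, and users
may supply their own grouping.

## Features

Each association carries five features, assumed conditionally independent
by the classifier:

| feature | type | meaning |
|---|---|---|
| `f_label` | binary | event on the comparator's label (snapshot in use at the test drug's approval) |
| `f_literature` | binary | event reported in literature for the comparator before the test drug's approval |
| `f_structure` | real | MACCS-166 Tanimoto similarity of the pair, or −1 if either drug is a biologic |
| `f_target` | real | cosine similarity of trivalent target-action vectors (+1/−1/0) |
| `f_market_years` | real ≥ 0 | comparator's years on the market at the reference date |

Design notes:

* The −1 biologic sentinel is an ordinary numeric value, not missing data:
  "no structure-based score exists" is itself informative and the
  classifier learns its class association.
* Pre-1982 approvals have no exact date in the registry; their market
  duration is imputed as exactly 36 years (1982 to the 2017 reference
  snapshot).
* Other durations use actual day counts / 365.25; no calendar convention
  beyond that is imposed.
* Market duration is measured to the analysis reference date (default
  2017-01-01, the reference-label snapshot date) rather than to each test
  drug's approval; the choice is configurable via `referenceDate`, and the
  two differ only by a per-pair constant offset.
* Similarity features are pair-level quantities; they are computed once per
  pair and broadcast across events.
* The target universe is the sorted union of targets in the loaded dataset,
  so target vectors are reproducible across runs. Cosine values are not
  clipped: the trivalent construction admits negatives, and a negative
  similarity is passed through as such.
* An all-zero∧all-zero fingerprint pair would make the Tanimoto ratio 0/0;
  it is defined as 0 (no shared substructure is claimed).
* Fingerprinting is pluggable: `maccsFingerprint()` delegates to
  OpenBabel/ChemmineOB by default but accepts any backend mapping SMILES to
  166-bit rows, and precomputed fingerprint matrices bypass SMILES
  entirely. Tests and the synthetic generator use the matrix path, so the
  chemistry toolkit is exercised only where it is the subject.

## Classifier

One Naive Bayes model is fitted per adverse event (not pooled across
events): event prevalences vary widely and the per-event prior is exactly
what carries that information. The training label is the test drug's
reference-date label for the event.

* Prior: the class-1 fraction of training rows.
* Binary features: categorical likelihood tables with a Laplace pseudo-count
  (`laplace`, default 0 to match the common reference implementation). A
  `binaryMode = "gaussian"` option treats them as numeric instead, since
  numeric-input implementations of Naive Bayes do so; categorical is the
  default.
* Continuous features: class-conditional Gaussians with means and sample
  standard deviations per class.
* Prediction: log-space accumulation of prior and likelihoods, normalized
  over the two classes. A pair votes positive when its posterior strictly
  exceeds 0.5 — an exact tie votes negative, the conservative direction for
  a pipeline that optimizes positive predictive value.
* Single-class training data (an event never or always present among
  training drugs) degrades, with a warning, to prior-only prediction.

### Numerical safeguards

Two degeneracies matter in practice and both are handled at well-defined
points:

* **Zero categorical cells.** With `laplace = 0` a feature value unseen in
  one class has empirical likelihood 0, which would veto the posterior
  outright. Exact-zero cells are replaced by `zeroGuard` (default 1e-3,
  the replacement threshold the reference implementation applies) at
  prediction time.
* **Collapsed Gaussians.** A class whose few training values coincide —
  which the 36-year market imputation makes common, since several
  comparators can share exactly 36.0 — would yield a zero standard
  deviation and a delta-function likelihood that both annihilates true
  votes elsewhere and manufactures spurious ones at the coincident value.
  Class-conditional standard deviations are therefore floored at
  max(`varFloor`, 0.1 × the feature's pooled standard deviation);
  `varFloor` (default 1e-9) remains the hard minimum for genuinely
  constant features, whose likelihoods then cancel between classes. At
  prediction, Gaussian log-densities are additionally bounded below by
  log(`zeroGuard`), so a single outlying continuous value cannot override
  the categorical evidence. The 0.1 fraction allows a class to be ten times
  sharper than the pooled spread before regularization engages; it is not
  exposed as a tuning knob.

## Vote aggregation and thresholds

A test drug's prediction for an event is the fraction of its comparators
voting positive; the event is called positive when 100 × fraction strictly
exceeds the threshold. Strictness matters at the bottom of the ladder: at
threshold 0 a drug needs at least one positive comparator vote — threshold 0
does not mean "always positive". Raising the threshold can only shrink the
positive set, so positive sets are nested along the ladder
0 < 10 < 30 < 50 < 60 < 70 < 90; the suite verifies this end to end. The
default operating point is 70, which maximizes the number of high-PPV
events on data of this structure while keeping predicted label changes
precise.

## Bootstrap evaluation

`bootstrapEvaluate()` repeatedly partitions the test drugs into a training
set (default 44) and a held-out set (default 10), drawn uniformly without
replacement and independently per iteration — with 10,000 iterations the
sampled partitions are a vanishing fraction of all possible ones, and
repeats across iterations are accepted. Per iteration and event, models are
refitted on training-drug rows, held-out drugs are predicted and aggregated,
and sensitivity, specificity, PPV and NPV are tabulated over the held-out
drugs. Since comparator votes do not depend on the threshold, votes are
computed once per iteration and every threshold's confusion counts are
derived from the stored vote fractions.

Summary conventions:

* Metrics are rounded half-up to integer percents **before** distribution
  summaries, so the mode lives on a discrete support.
* A metric with a zero denominator on an iteration is undefined: excluded
  from the samples and counted in `n_undefined`, never imputed (imputing 0
  would drag modes down artificially).
* Mode ties break toward the smallest value — conservative for the
  well-predicted call, so borderline events are not over-claimed.
* Median and quartiles use the nearest-rank rule on the sorted samples; no
  interpolation.
* An event is **well-predicted** when its PPV mode strictly exceeds 75
  (a left-skewed PPV distribution); an undefined PPV mode classifies as
  poorly predicted, with a warning.

Events present in fewer than two test-drug reference labels cannot support
training and evaluation and are excluded upfront
(`eligibleAdverseEvents()`; the threshold is parameterized with default 2).

## Leave-one-out safety-label-change evaluation

A (drug, event) combination is an issued safety label change when the event
is absent at approval and present on the reference-date label. `looSLC()`
trains on all test drugs but one, predicts the held-out drug at the chosen
threshold, pools combinations over all folds, and reports

* % of issued changes that were predicted =
  |changed ∧ predicted| / |changed|,
* % of predicted changes that were issued =
  |changed ∧ predicted| / |negative at approval ∧ predicted|,

each as an exact percentage with its numerator and denominator; a zero
denominator yields NA rather than a fabricated 0 or 100. Pooling over
combinations (not per-drug averaging) follows directly from the two
formulas.

## The synthetic-data generator

`generateDataset()` produces complete, referentially consistent datasets
with known ground truth. What it emulates, and the reasoning behind the
fixed design choices:

* **Pharmacological classes.** Test drugs carry 1–3 signed target actions
  (skewed toward a single primary target). Comparators inherit their test
  drug's full action set — which guarantees the defining shared same-sign
  action — plus Poisson(0.2) individual secondary targets. This mirrors
  class structure in real data, where a test drug's comparators are
  typically same-class drugs with nearly identical target profiles (the
  observed target-cosine mode in such cohorts is 1).
* **Planted signal.** Each planted event gets a driving target drawn among
  targets carried by at least max(2, 15% of test drugs) test drugs
  (falling back to the ≥2 minimum when the universe is sparse), weighted by
  squared carrier count: well-characterized target-event relationships
  belong to class-defining targets, not to targets hit by a single drug.
  Any drug acting on the driving target carries the event with probability
  `pEventGivenTarget` (default 0.9), all other combinations with
  `pEventBaseline` (default 0.05).
* **Fingerprints.** Each target has a random 166-bit template (25% density);
  a drug's fingerprint is the OR of its targets' templates with 12% per-bit
  noise. The noise level puts same-class Tanimoto scores near 0.5 on
  average — the level reported for real test-comparator cohorts — while
  keeping shared-target pairs clearly above unrelated ones.
* **Snapshots and literature.** The at-approval test snapshot deletes a
  configurable fraction (default 0.3) of reference positives, giving the
  SLC evaluator a known ground truth; literature evidence is the comparator
  label with independent flips (default rate 0.1) per (comparator, test)
  pair.
* **Registry.** Test drugs are approved 2008–2013 (the structured-label
  era); comparators span 1982–2012 with a configurable fraction (default
  0.3; 0.37 at study scale) flagged pre-1982 and imputed to 36 market
  years. A `biologicFraction` of drugs are biologics with no fingerprint.
* **Seeding.** All randomness derives from one master seed through named
  substreams (one per table), so adding a table leaves existing ones
  unchanged and generation is byte-reproducible.

`defaultStudyScale()` configures a 54-test-drug cohort: comparator counts
1–37 drawn with a k^−1.5 skew (mode 1–2), 135 events over 30 class-defining
targets, 40 planted associations. With these settings the generated cohort
reproduces the distributional summaries reported for real cohorts of this
design — modal comparator count 1, mean same-class Tanimoto ≈ 0.5, about a
third of comparators at the 36-year imputation — and the threshold sweep
reproduces the qualitative trade-off: the share of issued label changes
predicted falls with threshold while the share of predictions that are real
rises, with the high-PPV event count peaking at intermediate-to-high
thresholds.

**What the generator does not emulate.** Comparators are generated per test
drug and never shared between test drugs, so there are no cross-test
correlations from a comparator appearing in several classes. Event
baselines are homogeneous, whereas real prevalences vary by orders of
magnitude across events (real cohorts lose ~20% of events to the
two-label eligibility rule; the synthetic study-scale cohort loses almost
none). Tanimoto scores span a narrower range than real chemistry
(about 0.3–0.8 versus 0.02–1), and mean target cosine stays near 1 because
full class profiles are inherited. Passing tests on this generator
therefore demonstrate that the pipeline recovers target-driven signal of
known strength under controlled noise — not that any particular real-world
performance level will be attained.

## Problem sizes used by the test suite

The suite runs the bootstrap at reduced but structurally faithful sizes,
chosen as the smallest scales at which the statistical claims are stable:
planted-signal recovery uses 20 test drugs with 1–5 comparators each, 30
events (10 planted), 500 iterations with a 16/4 split; the study-scale
smoke test runs 54 drugs at 1,000 iterations. The acceptance script runs
the study-scale cohort at 1,000 iterations across the full threshold
ladder.

## Known limitations

* The comparator label is a single snapshot matrix; in reality each
  comparator's label should be read as of each test drug's approval date.
  Dated label retrieval is upstream of this package, and the literature
  table — which is keyed per (comparator, test) pair — is where
  approval-date-dependent evidence enters.
* Boxed-warning versus adverse-reactions placement on a label is not
  distinguished; presence anywhere counts once.
* Low-prevalence events (present in just two or three test-drug labels)
  have weakly determined priors and class-conditional densities; their
  bootstrap distributions are wide and heavily `n_undefined`, and calls on
  them should be read accordingly.
* The classifier's independence assumption is knowingly violated
  (`f_label` and `f_literature` are correlated); as usual with Naive Bayes
  this biases posteriors toward extremes but rarely flips the vote
  ordering.
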