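---
title: "Stage classification from RNA expression: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage classification from RNA expression: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncostage)
```

`oncostage` builds and evaluates tumor-stage classifiers from bulk RNA-seq
FPKM matrices. This vignette is the package's own account of its methods:
what each model assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open and a choice had
to be made.

## The data model

The unit of analysis is an FPKM expression matrix (transcripts × samples,
non-negative, with structural zeros) accompanied by a clinical table
assigning each sample a stage. Stages I and II are pooled as **early**,
III and IV as **late**; adjacent non-tumorous samples form a third
**normal** class. Pooling reflects the clinical watershed between disease
confined to the organ and disease that has spread — and it doubles as a
variance-reduction device, since per-stage sample counts are too small for
four-way classification at typical cohort sizes.

All modelling happens on the log2 scale, x = log2(FPKM + 1). The
pseudocount keeps transformed values non-negative and maps structural
zeros to exactly 0; effects that are additive on this scale are fold
changes on the raw scale, which is the natural effect geometry for
expression data.

The preprocessing order is fixed: log2 transform → variance filter →
Z-score. The variance filter (sample variance with the n−1 denominator)
defaults to 0.25 for the early/late task and 0.02 for the cancer/normal
task; the cutoffs are interpretable only because the denominator
convention is fixed and recorded. Z-scoring always uses **training**
means and standard deviations, frozen into the model and applied
unchanged to held-out or external data — using the target's own moments
would leak the test distribution into the decision rule. Zero-variance
transcripts that survive filtering are flagged at fit time and refuse to
be Z-scored rather than silently producing infinities.

## Single-transcript threshold models

The package's core primitive asks, for one transcript: how well can a
single expression cut-point separate the two classes? The rule is
directional — the class with the greater mean expression is assigned to
samples at or above the threshold, the other class below it — and the
threshold is swept over every observed expression value from the minimum
to the maximum. Each candidate is scored by the **point AUROC**,

$$\mathrm{AUROC}(t) = \tfrac{1}{2}\left(\mathrm{sens}(t) + \mathrm{spec}(t)\right),$$

which is exactly the trapezoidal area under the three-point ROC curve
{(0,0), (FPR(t), TPR(t)), (1,1)} of the fixed-threshold classifier. Two
readings of "the AUROC of a threshold model" are possible — this
per-threshold area, or the full-curve AUROC of the underlying continuous
score — but only the first depends on the threshold at all, so only the
first can be the quantity a threshold sweep maximizes; the package adopts
it. The optimum can never fall below 0.5, because the cut at the minimum
observed value reproduces the degenerate all-one-class rule.

Numerical conventions: candidate thresholds are the observed unique
values with an inclusive ≥ rule (no midpoint grid); ties in the maximum
are broken toward the smallest threshold, which is deterministic and
favors sensitivity for positive-direction features; a transcript with
exactly equal class means keeps direction `positive_high` and is flagged
degenerate. One consequence worth knowing: because the direction is fixed
by the class *means*, the optimal point AUROC is invariant under positive
affine transforms of the expression values, but a general strictly
increasing transform can flip the mean ordering and with it the rule's
direction. That is a property of the published rule itself, not an
artifact of this implementation.

Transcripts are ranked by optimal point AUROC (ties broken
lexicographically by ID for reproducibility), and panels are cut at an
inclusive AUROC threshold — 0.60 by default for the stage task (the
weakest cutoff that still beats random features), 0.85 for the much
easier cancer/normal task. The ranked table carries class means, the
optimal threshold, and a two-sided Wilcoxon rank-sum p-value per
transcript: exact when the pooled sample size is ≤ 25 with no ties, the
tie-corrected normal approximation otherwise, with Benjamini–Hochberg
adjustment across the table. BH was chosen as the transcriptome-screen
default; the source analyses report "adjusted" p-values without naming a
method, so this is recorded as an assumption.

## Feature selection

Four selectors with different inductive biases operate behind a common
panel interface:

* **FCBF** (fast correlation-based filter). Features are first
  discretized by recursive entropy-minimizing splits accepted under the
  Fayyad–Irani MDL criterion; features that stay in a single bin carry no
  class information at any threshold and are never selected. Relevance is
  symmetrical uncertainty with the class, SU = 2·I/(H+H); redundancy
  elimination keeps a feature only if no stronger already-kept feature
  predominates it (SU between features ≥ SU with the class). The
  relevance threshold defaults to 0 — keep everything relevant, prune
  everything redundant.
* **ANOVA-F top-k**: the classical one-way F statistic per feature; for
  two classes it equals the squared pooled t statistic (a property the
  test suite checks numerically).
* **L1 margin selection**: a linear classifier with squared-hinge loss
  and an L1 penalty (intercept unpenalized), fitted by FISTA; the panel
  is the support of the weight vector (|w| > 1e−8), ordered by |w|. The
  penalty yielding a given panel size is data-dependent, so a bisection
  helper (`l1_select_size`) is provided; the selection path is observed
  (and tested) to be non-increasing in the penalty, though exact
  monotonicity is not guaranteed for L1 paths in general.
* **Stochastic subset search**: a seeded population search over binary
  feature masks (tournament selection, uniform crossover, per-bit
  mutation, elitism) whose fitness is the mean 10-fold cross-validated
  MCC of an RBF margin classifier on the masked features. This is a
  generic stand-in for wrapper searches built on specialized
  metaheuristics: it keeps the same encoding (a ≤100-bit mask) and the
  same objective, while remaining seed-reproducible and
  dependency-free. Fold assignment is fixed per call and fitness values
  are cached, so repeated masks cost nothing.

## Classifiers

The deployable unit bundles a feature panel, training-frozen
normalization statistics, a fitted RBF-kernel margin classifier with
monotone (sigmoid) probability calibration, the class list and a decision
threshold — everything needed to score a raw FPKM matrix. Hyperparameters
come from a stratified k-fold grid search; the default grid is
log-spaced γ ∈ {10⁻³, 10⁻², 10⁻¹, 1, 10} and integer C ∈ {1, …, 10},
spanning the conventional ranges; ties resolve toward the smaller cost,
then the smaller γ (flatter models when accuracy is equal). The decision
threshold defaults to 0.5; `choose_decision_threshold` instead selects
the operating point minimizing |recall − specificity| (ties: maximum
accuracy, then smallest threshold), the "balanced" operating point a
screening tool would present. Scores at exactly the threshold are called
positive.

Multiclass classification is one-vs-rest: one calibrated binary scorer
per class, predicted class by argmax, per-class score vectors exposed so
each class gets its own ROC. Cross-validation is stratified with every
sample tested exactly once (pooled confusion totals n); leave-one-out is
the k = n special case, used for small down-sampled comparisons.

Models persist as plain-text archives (manifest JSON, panel TSV,
normalization TSV, deparsed classifier parameters); the round trip
reproduces predictions exactly, which the suite asserts.

## Evaluation

All metrics derive from TP/FP/TN/FN: sensitivity, specificity and
accuracy as percentages; precision and recall as fractions; MCC with the
standard four-factor denominator, defined as 0 whenever a marginal factor
vanishes (constant predictions carry no correlation). Binary "F1" is
reported in all four aggregations — per-class, macro, support-weighted
and micro — because published tables are often ambiguous about which they
print; for a complete binary confusion, micro-F1 equals accuracy, which
is the reading consistent with most such tables. Undefined ratios
(zero denominators) are reported as undefined-with-reason rather than as
propagating NaNs.

AUROC is computed two ways — trapezoidal integration over score
thresholds and the normalized Mann–Whitney statistic with tied pairs
counted ½ — and the implementations are asserted equal before the value
is returned; the suite also cross-checks against an independent ROC
implementation. Confidence intervals use a stratified percentile
bootstrap (positives and negatives resampled separately; 2,000
replicates at 95% by default; degenerate one-class resamples are redrawn)
— an analytic CI is deliberately out of scope.

PPV/NPV tables use dual cut-offs: at cut-off t, samples scoring ≥ t are
called positive and samples scoring ≤ 1 − t are called negative, with the
band in between abstaining. This is the semantics under which published
call counts at stringent cut-offs fail to partition the cohort — both
call sets shrink as t rises. Empty call sets report 0 with an explicit
flag rather than NA, matching how such tables are printed. A 1e−9
tolerance guards the complementary cut-off against floating-point
rounding (1 − 0.9 is not representable exactly).

## The synthetic-data generator

The generator is the stand-in for the TCGA-style cohorts the pipeline
targets, and its defaults are the study conditions: 333 early / 167 late
/ 58 normal samples, 36 planted stage-informative transcripts at a
1.5-sd log2 effect, and 2,000 transcripts — scaled down from the
transcriptome-wide 60,483 so that a full ranking runs in under a second;
problem sizes in the tests and the acceptance script follow this
desk-scale choice. Per transcript, a baseline log2 abundance is drawn
from N(3, 1.5²); per sample, the log2 level adds a class shift and
N(0, 1) noise, and FPKM = 2^level − 1 clipped at zero. Planted
transcripts shift the late class by ±1.5 sd (alternating directions) and
the normal class by ∓2.5 sd, giving a monotone normal → early → late
progression along each planted axis — the cancer/normal contrast is
deliberately stronger than the stage contrast, as observed in real
cohorts where tumor/normal separation is far easier than stage
separation. Five percent of entries are zeroed to emulate structural
dropout, which stresses the log2 pseudocount and the variance filter.

External cohorts are simulated by keeping a configurable fraction of
features (never less than half the planted truth set), applying a
per-feature monotone platform distortion (scale ∈ [0.6, 1.4], offset ∈
[−1, 1] on the log2 scale), and drawing fresh samples — 17 early / 3 late
by default, the shape of a small published external stage cohort.
Feature-specific quantile normalization onto the training reference
undoes any strictly monotone distortion exactly (rank correlation 1);
where clipping at zero or dropout has collapsed ranks, exact restoration
is impossible by construction, so the harmonization checks use a
no-dropout, high-baseline configuration in which the platform map is
strictly monotone.

What the generator does **not** emulate: gene–gene correlation structure,
batch effects, library-size artifacts, or real transcript identifiers.
Passing recovery tests on this generator therefore demonstrates that the
pipeline's machinery is correct and calibrated under independent planted
signals — not that any particular panel size or AUROC will be achieved on
real cohorts, where correlated features make both selection and
classification harder.

## Splitting and reproducibility

The stratified 80:20 split stratifies on the original four-level stage
(plus normal), not on the pooled early/late label, and takes exactly
⌊0.8·n⌋ samples per stratum into training. Flooring matters: on stage
counts 281/52/112/55/58 it yields training sizes 224+41 = 265 early,
89+44 = 133 late and 46 normal — the sizes a per-stage 80% split
produces in the motivating analyses — whereas rounding would not. Every
stochastic component (splits, folds, bootstrap, the generator, the
subset search) is seeded explicitly and never disturbs the caller's RNG
state; every pipeline run writes its resolved configuration next to its
outputs, and reruns with the same configuration are byte-identical.

## Known limitations

* The threshold-model AUROC is a training-resubstitution quantity; with
  ~2,000+ candidate transcripts the top of the ranking is optimistically
  biased, which is why multi-transcript panels are validated on held-out
  splits.
* The L1 selector's panel size is controlled only indirectly through the
  penalty; the bisection helper finds the closest attainable size, which
  may not be exact.
* Probability calibration is fitted within the training folds of the
  margin classifier; scores are monotone in the decision value but not
  guaranteed to be well-calibrated on small validation sets.
* The subset search is a stochastic heuristic: it is seed-reproducible
  but makes no optimality guarantee beyond containing the best mask it
  evaluated.
* Stage labels are treated as ground truth; label noise in clinical
  staging is not modelled.
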