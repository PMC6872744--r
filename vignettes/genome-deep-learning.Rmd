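---
title: "Variant-based cancer classification with gdlnet: model and methods"
author: "gdlnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant-based cancer classification with gdlnet: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdlnet)
```

## The problem

Cancer genesis is accompanied by an accumulation of somatic mutations, and
cohort studies show that much of that accumulation is recurrent: a minority
of variant sites appear again and again within a tumor type. `gdlnet`
implements the genome-deep-learning (GDL) approach to exploiting this
structure: classify a sample's phenotype (a specific cancer type versus
healthy, any cancer versus healthy, or one of several cancer types) from
nothing but the *presence or absence* of point mutations at a ranked panel
of recurrent sites.

Three task modes are supported, matching the three classifier families of
the approach:

* **specific** — one cancer type versus healthy (binary);
* **total** — pooled cancer versus healthy (binary);
* **mixture** — which of C cancer types (multi-class).

## Feature construction: the Mutation Collection

Every sample enters as a VCF of point mutations. A variant's identity is
the exact tuple (chromosome, position, ref, alt) with the chromosome name
normalized (`chr17` equals `17`) and multi-allelic records split. No
left-alignment or indel normalization is attempted: SNVs are the intended
input, identity is literal string match, and any normalization difference
is something to surface upstream, not to silently repair. Coordinates stay
1-based throughout. Genotype columns are ignored — the method's encoding is
purely presence/absence, so a record's existence means the sample carries
the site.

The **Mutation Collection** is the ordered panel of feature sites. Each
candidate site is scored by its *occurrence*: the number of distinct
cohort samples carrying it ("occurrence in the cancer group" is read as
sample frequency, the HapMap-style convention, not as mutation-event
count). Sites are ranked by occurrence descending; ties are broken by
genomic order, which makes the ranking — and every downstream artifact —
deterministic across runs and platforms. Two selection rules exist:

* `top_k`: keep the k best-ranked sites. Used for specific models (the
  full-scale reference protocol uses k = 10,000; the package default for
  its synthetic studies is 1,000).
* `min_occurrence`: keep sites whose count is **strictly** greater than m.
  The pooled-cohort rule for total and mixture models uses m = 2, so a
  site must appear in at least 3 samples.

Specific-model panels are built from the case cohort only; a
control-private site can therefore never become a feature dimension. A
sample `x` encodes against a panel of sites `s_1..s_d` as the binary vector
with `x_j = 1` iff the sample carries `s_j`. Labels are one-hot encoded in
the order the class vocabulary was declared, and that order is persisted
with every dataset and model.

## The classifier

The network is a stack of fully connected layers. Each unit computes the
weighted sum of its inputs plus a bias, `y = f(sum_i w_i x_i + b)`, with
the ReLU activation `f(x) = max(x, 0)` on hidden layers. The output layer
is linear and feeds a softmax stage,
`p_i = exp(y_i) / sum_j exp(y_j)` (computed with max-subtraction so large
scores cannot overflow), giving a class probability distribution. The loss
is the cross-entropy `H(p, y') = -sum_i y'_i log p_i` against the one-hot
truth, with natural logarithm; predictions are clipped to `[1e-12, 1]`
before the logarithm, so a maximally wrong prediction costs about 27.6
nats instead of infinity. An L2 penalty `lambda * sum(w^2)` over all
weight matrices (biases excluded) is added to discourage memorizing noisy
labels; its gradient contribution is exactly `2 * lambda * w`.

The architecture ships with four ReLU hidden layers plus the softmax
output stage. Hidden widths are not canonical to the method; the default
pyramid is `c(512, 256, 128, 64)` for ~10,000-dimensional inputs, and the
package's own synthetic studies use `c(64, 32, 16, 8)` for their
1,000–7,000-dimensional panels. Both are plain configuration. (Whether
"four fully connected layers" should count the output layer is genuinely
ambiguous; this implementation uses four *hidden* layers plus a linear
output layer and exposes the count as configuration, so either reading is
available.)

Weights initialize from a truncated Gaussian (±2 sd, sd = 0.1) and biases
at 0.1, seeded; these mirror the conventional defaults of the
deep-learning frameworks of the method's era and are recorded in every
run's config.

## Optimization

Training is plain minibatch gradient descent on the regularized loss —
deliberately so: no momentum or adaptive variants, because the method is
defined with gradient descent plus three specific refinements:

1. **Exponential learning-rate decay.** At global step g the rate is
   `R = r * d^(g/s)` with base rate r, decay rate d and decay period s; a
   staircase flag replaces `g/s` with `floor(g/s)`. Defaults:
   r = 0.1, d = 0.96, s = 200.
2. **L2 regularization** as above, default `lambda = 1e-4`.
3. **Shadow (sliding-average) parameters.** Every parameter V keeps a
   shadow copy S, updated after each optimizer step as
   `S = d*S + (1-d)*V` with d = 0.99. Under a constant V the shadow
   converges geometrically, `S_t = V (1 - d^t)`. All inference uses the
   shadow copies; live parameters exist only inside the training loop. The
   literal update rule is used — no update-count warm-up correction of the
   kind some frameworks layer on top.

Gradients are exact reverse-mode derivatives of mean cross-entropy plus
the L2 term (the softmax/cross-entropy head contributes the classic
`p - y` residual), and the test suite checks them against central finite
differences at 1e-5 relative error across 100 seeded networks. Minibatches
are sampled without replacement per step from the training rows, driven by
a single seed: two runs with the same data, config and seed produce
bit-identical parameters.

Batch size defaults to 128 at full scale (32–64 in the synthetic studies)
and `max_steps` to 5,000 (300 for specific, 600 for mixture models in the
synthetic studies — the point where the loss trace has flattened on those
cohorts, recorded as the study's problem size).

## Evaluation battery

Binary models use the threshold decision rule — predict the positive class
iff its probability is *strictly* above the threshold (default 0.5) — and
report accuracy, sensitivity `tp/(tp+fn)` and specificity `tn/(tn+fp)` as
percentages, with the raw confusion counts. The ROC is computed by
sweeping the threshold over the unique scores (ties grouped into a single
step) and the AUC by the trapezoidal rule; the suite cross-checks it
against the Mann–Whitney rank-statistic formulation at 1e-9. ROC plotting
defaults to the conventional FPR/TPR axes; a `mirrored` flag plots
sensitivity against specificity for reports that use that orientation (the
area is unchanged).

Multi-class models report argmax accuracy (ties broken by lowest class
index, documented and deterministic), a predicted-by-true confusion
matrix, one-vs-rest sensitivity/specificity per class, and top-N accuracy
for N = 1..C. Because the macro/micro choice for an aggregate specificity
is a genuine convention fork, both are reported.

`aggregate_model_metrics()` summarizes a battery of binary models as mean
and **sample** (n−1) standard deviation. That estimator choice is pinned
by a reference check: aggregating the published per-model table of the
twelve cancer-specific classifiers (`gdl_reference_metrics()`) reproduces
the published summary pairs — 98.70/0.91 accuracy, 98.36/1.34 sensitivity,
99.03/0.7404 specificity — which the population estimator does not. (One
wrinkle: the published accuracy SD 0.91 truncates the computed 0.9191
rather than rounding it; the tests therefore require agreement to one unit
in the last printed digit.)

`shared_dimension_matrix()` counts panel sites common to each pair of
collections — the diagnostic used to ask whether cancers with heavily
overlapping panels are the ones a mixture model confuses.

## The synthetic cohort simulator

Real cohorts at the method's scale are controlled-access, so the package
ships a generator that reproduces the *statistical shape* the method
assumes, making the whole pipeline testable offline:

* each cancer class has `n_signature` planted signature sites, carried by
  its samples independently with probability `penetrance`;
* all samples, healthy included, carry each of `n_background` background
  sites independently at `bg_rate`; healthy samples carry background only;
* optional pairwise overlap plants shared signature sites between named
  classes (implemented by sharing a prefix of the donor class's panel, so
  configured fractions are hit exactly);
* coordinates cycle the 22 autosomes with positions spaced ≥ 100 apart, so
  synthetic keys are valid and collision-free.

The standard evaluation cohort is 12 cancer classes plus healthy, 100
samples per class, 200 signature sites per class at penetrance 0.9, and
5,000 background sites at rate 0.02 (a signature-to-background contrast
wide enough that frequency ranking is informative but background sites
still enter pooled panels, as in real cohorts where recurrent sites sit on
a long low-frequency tail).

**Why the default overlap includes a fully shared pair.** Sites here are
independent Bernoulli draws, so two classes sharing any fraction
strictly below 1 of their signatures still differ on the remaining unique
sites, and at 100 samples/class a trained network separates them
essentially perfectly — partial overlap alone cannot produce the
qualitative gap in which a mixture model trails the specific models. The
regime of genuinely confusable cancer types therefore requires a pair
whose panels coincide: the default makes UCEC and COAD (the pair with the
largest shared panel in the method's reference analysis) share their full
signature set, plus 0.6 partial sharing with BRCA. With that structure the
12-way mixture model's test accuracy lands around 90–95% against ~100% for
every specific model, the errors concentrate in the UCEC/COAD block of the
confusion matrix, and top-2 accuracy recovers to ~100% — the qualitative
fingerprint of the full-scale results, at desk scale.

What the simulator does **not** emulate: linkage between sites, mutational
signatures and trinucleotide context, tumor heterogeneity/subclonality,
purity, coverage-dependent false negatives, or population structure in the
healthy cohort. Passing the end-to-end tests therefore demonstrates that
the pipeline recovers planted structure of the assumed form — not that the
method attains any particular accuracy on real tumors.

## Numerical and design choices

* Softmax uses max-subtraction; cross-entropy clips at 1e-12; non-finite
  training loss aborts with a hint rather than propagating NaN.
* Ranking ties (equal occurrence counts), argmax ties and top-N ties all
  break deterministically (genomic order, lowest class index).
* Stratified splits take `round(fraction * n)` training samples per class,
  clamped so both partitions are non-empty; a class with fewer than 2
  samples is rejected by name. The shuffle depends only on the seed.
* FILTER handling (PASS/`.` only) is a flag because calling pipelines
  differ in how they use the column; symbolic alleles are skipped and
  counted, never guessed at.
* All-zero encodings (a sample sharing nothing with the panel) are legal
  and retained — for control samples against a case-derived panel they are
  the expected signal — but they are flagged with a warning, since for
  case samples they usually mean a chromosome-naming or panel mismatch.
* Model archives embed the panel's site list; prediction against a
  dataset encoded with any other panel fails loudly rather than returning
  misaligned probabilities.

## Problem sizes used by the shipped studies

The test suite and the acceptance script run the standard cohort above
with top-K panels of 50–1,000 sites for the twelve specific models (about
7,000 pooled dimensions for the mixture model), hidden widths
`c(64, 32, 16, 8)`, 300/600 training steps, and batch sizes 32/64. These
sizes were chosen as the smallest at which the planted structure is
recovered cleanly and the loss traces flatten; they are the package's
standard study conditions, and the full-scale defaults remain available
through the same configuration objects.

## Limitations

* Variant identity is literal; indels that differ only in normalization
  are distinct features.
* The classifier has no calibration guarantee; thresholds other than 0.5
  are the user's judgement.
* Plain SGD with the shipped schedule is adequate for the binary-encoded,
  high-signal inputs the method targets, but no claim is made that it is
  the fastest route to convergence on other feature families.
* The comparison battery stops at descriptive metrics; statistical tests
  between classifiers (DeLong and friends) are out of scope.
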