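---
title: "Classifying multi-view image sets: models, consensus labels and hierarchical evaluation"
author: "toothset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying multi-view image sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothset)
```

## The problem

An isolated tooth carries no positional context: no neighbours, no jaw, no
radiograph. Identifying its FDI class from appearance alone is hard even
for experts, because the discriminative anatomy is distributed across
viewpoints — cusp pattern on the chewing surface, root configuration on
the sides, crown/root proportions in profile. `toothset` treats this as an
*image-set classification* problem: one label is predicted from a set of
six photographs taken from standardized directions (occlusal, apical,
buccal, lingual, mesial, distal), and the package generalizes to any
problem with the same shape (a fixed set of tagged views per specimen).

Three difficulties shape the design:

1. **Evidence is split across views.** No single photograph suffices; the
   classifier must fuse complementary evidence.
2. **The true class can be unknowable.** Worn or atypical specimens admit
   no certain label, so reference labels are themselves estimates. A
   weighted-vote consensus over several raters produces
   *pseudo-ground-truth* (P-GT) labels and removes specimens on which no
   qualified majority exists.
3. **Fine labels are unreliable at the boundaries.** Evaluation therefore
   runs at three nested granularities — 16 classes (`U1`–`U8`,
   `L1`–`L8`), 6 groups (jaw × anterior/premolar/molar) and 3 groups
   (anterior/premolar/molar) — obtained by merging, never by retraining.

## The set classifier

Each view image is letterboxed to a square model input: scaled so its
longer side matches the input side, aspect ratio untouched, and padded
with black. Aspect ratio is itself an anatomical cue (crown/root
proportion), so it is never distorted. Padding is centered, with an odd
leftover pixel on the trailing edge — placement is a free choice and
centering keeps the specimen in the middle of the receptive field.

A single convolutional encoder — *shared across all six views* — maps
each image to a `d`-dimensional feature token (`d = 512` at full scale).
The `tiny` encoder is four stride-2 convolution stages followed by global
average pooling and a linear projection; `convnext_s_like` is the same
machinery at the stage widths of a ConvNeXt-S-scale backbone
(96/192/384/768 channels) for users with the compute to train it, without
pretrained weights. The six tokens, plus a learned aggregation token, pass
through a transformer-style attention encoder (default: 2 post-norm
blocks, 8 heads, feed-forward width `4d`, ReLU). The aggregation token's
final state is the *set embedding* — the representation exported for
visualization — and a linear softmax head turns it into class
probabilities. Alternatives kept behind flags:

* `pooling = "mean"` averages the view tokens instead of using a learned
  token; combined with `view_embedding = FALSE` the whole set function is
  permutation-invariant, which the test suite exploits.
* `view_embedding = TRUE` (default) adds a learned per-view-tag embedding
  to each token. The six views are semantically distinct, so the model
  should know which token is which; permuting tokens together with their
  embeddings provably leaves the output unchanged (equivariance), and this
  is tested by direct computation.

### Feature standardization between encoder and fusion

Encoder outputs are standardized per dimension (mean 0, sd 1) before
fusion, using statistics computed once on the training set and stored as
non-trainable buffers. This came out of a concrete failure mode: classes
that differ only in *cross-view combinations* of attributes give the
fusion a learning signal that lives in a few directions of feature space,
at whatever scale the untrained encoder happens to emit. When that scale
is small relative to the token norm, gradient descent settles into the
symmetric saddle where both classes of a complementary pair receive equal
probability — and the encoder then *shrinks* its output variance further,
because shrinking reduces the loss of confidently wrong predictions.
Standardization removes the scale pathology; it is on by default and can
be disabled (`feature_norm = FALSE`).

### Encoder freezing as a warm start

`train_config(freeze_encoder_epochs = k)` keeps the encoder at its
initialization for the first `k` epochs while the fusion and head train
alone (cheaply — features are cached when no augmentation is active),
then fine-tunes everything jointly. Random convolutional features
preserve the image statistics, so the attention module can learn
cross-view relationships on a stationary representation before the
encoder starts reshaping it. The default is 0 (plain joint training); the
small-scale benchmark uses 5 of its 10 epochs.

## Training recipe

Defaults follow the study's recipe: Adam with decay rates (0.9, 0.99),
weight decay 0.5 applied to weight matrices only (not biases or
normalization parameters; decoupled by default — an unusually large value
that interacts with the decay convention, so both conventions are
supported), batches of 16 specimens (96 images), 300 epochs, label
smoothing 0.1 spread over all classes including the true one, and a
per-step learning-rate schedule: linear warmup over 60 epochs, then
`base_lr * (1 - progress)^1.5` down to zero. Two values are package
choices rather than part of that recipe and are flagged as such in the
documentation: the base learning rate (default `1e-4`; never stated for
the original experiment) and all augmentation magnitudes.

Augmentation applies four spatial transforms independently per image with
probabilities 0.5 / 0.2 / 0.2 / 0.2: rotation (±15°), *dropout* read as
image-level occlusion (cutout, ≤10 % area) since it is listed among
spatial transforms, perspective distortion (corner displacement 0.2), and
affine translate/scale (≤10 %, 0.9–1.1). Augmentation draws are
independent per image by default; `set_consistent_augment`-style behavior
can be had by deriving one seed per specimen. Evaluation paths never
augment.

## Consensus refinement

Four annotations per specimen — two reliable (weight 2 each) and two less
reliable (weight 1 each) — vote for categories. A specimen is accepted
with P-GT label `c` iff `score(c) ≥ 4` and `c` is the unique maximum;
otherwise it is removed as ambiguous. With total weight 6 and threshold
4, two categories can never reach the threshold simultaneously (that
would need total ≥ 8), so no tie-break is ever exercised under the
defaults; the suite enumerates all 16⁴ = 65,536 assignments and checks
exact equivalence with the independent two-condition restatement (*the
two reliable raters agree*, or *one of them agrees with both others*).
Weights and threshold are configuration; for non-default settings where a
tie at the threshold is possible, the specimen is removed — the
conservative reading of a procedure whose purpose is filtering ambiguity.

## Evaluation protocol

All metrics are computed at each granularity from one fine-level model:

* **Top-k accuracy** uses the rank of the true class among descending
  probabilities; ties resolve in favor of the true class (deterministic,
  and measure-zero for real models).
* **Coarse granularities** merge fine-class *probabilities* by summing
  group members (the default report), with the accuracy of merged
  *argmax labels* reported alongside. The two differ in a subtle way:
  merged-label top-1 is provably never below fine top-1 (a fine hit stays
  a hit), but merged-probability top-1 can dip below it when a group
  accumulates several small probabilities past the true class. The
  property tests assert monotonicity for the label-merge route.
* **Sensitivity/specificity** come from one-vs-rest counts with macro
  (unweighted per-class) averaging; classes with zero support are
  excluded from macros with a warning — a synthetic-data situation, as
  real test sets populate all classes.
* **ROC/AUC** per class by threshold sweep and trapezoid rule, macro AUC
  as the mean of defined per-class AUCs; degenerate classes yield `NA`
  (serialized as `null`). The sweep is verified against exhaustive
  concordant-pair counting on every random instance up to N = 50.
* **Cohen's κ** (model vs P-GT) uses marginal-product chance agreement
  and an asymptotic 95 % CI; if both labelings are the same constant,
  κ is defined as 1 and flagged.
* **Fleiss' κ** (among raters) uses the standard category-proportion
  formulation; its CI is a percentile bootstrap over specimens (2,000
  resamples, seeded) — a deliberate choice, since the reference tables
  report CIs without naming a method and resampling specimens makes no
  distributional assumption.

## The synthetic data generator

No tooth photographs are distributed with the package, so the generator
stands in for them with procedural 2-D renderings designed to reproduce
the *structure* of the problem rather than its appearance: a filled crown
with bright cusp bumps in the two top-down views (cusp count invisible
from the side), root stems below the crown in the four side views (root
count invisible from above), crown/root ratio and a signed bowing of the
occlusal edge as the upper/lower-jaw cue. Two rendering choices matter
for learnability and were made deliberately: root stems have constant
width so that total bright area grows with root count (a count-invariant
area would be invisible to average-pooling feature extractors), and
class-coding structures are large and high-contrast so they survive heavy
downscaling. Rendering is deterministic given (spec, view, seed); all
randomness derives from one root seed via counter-based hashing, so
results do not depend on generation order. Default images are 256 × 192 —
deliberately non-square so the letterbox path is always exercised.

The **separable 4-class preset** contains a designated
*view-complementary pair*: `P1` mixes variants (3 cusps, 1 root) and
(4 cusps, 2 roots), `P2` mixes (3, 2) and (4, 1). Both classes show cusp
counts {3, 4} from above and root counts {1, 2} from the side — identical
single-view marginals — yet the cross-view pairing identifies the class
exactly. A Bayes-optimal classifier is perfect with all six views and at
chance on the pair from any single view, which the suite checks by
exhaustive attribute comparison. The **16-class preset** maps position
(1–8) to a gradient of cusp/root counts and crown/root ratios and encodes
the jaw only in the side-view curvature, so fine classification again
requires both view families.

Simulated annotators draw labels from row-stochastic confusion matrices
whose off-diagonal mass concentrates on adjacent positions in the same
jaw and on the opposite-jaw counterpart — the error structure real
observers show — with two reliable raters (diagonal 0.85) and two noisier
ones (0.70). What the generator does *not* emulate: photographic
appearance, lighting and background variation, occlusion, intra-class
anatomical variability beyond parametric jitter, or rater biases that
correlate across raters. Passing tests on synthetic data therefore
demonstrate that the machinery is correct and that set fusion beats
single views *when evidence is view-distributed* — they say nothing about
accuracy on real photographs.

## The small-scale benchmark

`run_separable_benchmark()` is the package's standard capability check
and the problem size used throughout testing: 4 classes × 70 specimens
(200 train / 80 test), input side 64, embedding 32, two fusion layers of
four heads, batch 8, base learning rate 3e-3 (poly 0.9, one warmup
epoch), weight decay 0.05, label smoothing 0.1, five frozen epochs out of
ten, no augmentation. These values are the package's small-scale study
design: the full-scale defaults (224 px, `d` = 512, 300 epochs, weight
decay 0.5) belong to the original recipe and are not appropriate for a
ten-epoch run on 200 specimens. The benchmark trains the set model and an
occlusal-only baseline with the identical recipe; the margin on the
`P1`/`P2` pair isolates the contribution of multi-view fusion.

## Numerical and degenerate-input choices

* Gradients for every layer are hand-derived and validated against
  central finite differences in the test suite (relative error < 1e-4).
* Softmax and cross-entropy are computed with max-shifted logits.
* Rank ties (top-k) favor the true class; `max.col` ties in predictions
  resolve to the first class in taxonomy order, fixed as `U1..U8,
  L1..L8` so confusion matrices are comparable across runs.
* Zero-area images, missing or duplicate view tags, unknown labels,
  non-stochastic confusion rows and non-finite logits all raise immediate
  errors naming the offender.
* Augmentation with degenerate magnitudes reduces to the identity;
  probabilities are validated to [0, 1].
* FDI two-digit codes (11–48) are normalized to jaw + position on load;
  left/right is never represented.

## Known limitations

* The renderer is a structural surrogate; no claim transfers to real
  photographs without retraining and re-evaluation.
* Training is single-threaded CPU R; the full-scale configuration
  (224 px, `d` = 512, 300 epochs) is defined and functional but intended
  for small runs only at this implementation's speed.
* The consensus module implements fixed-weight voting only — rater
  ability is not estimated (no Dawid–Skene-style EM), matching the
  procedure it reproduces.
* Re-annotation timing (rounds collected years apart) is not modeled;
  extra annotation rounds are simply extra rater columns.
* `convnext_s_like` reproduces stage widths, not the depthwise block
  design, and loads no pretrained weights.
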