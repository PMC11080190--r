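# toothset

Multi-view image-set classification with attention fusion, consensus
label refinement and hierarchical evaluation — built around the problem
of identifying isolated human teeth from six standardized photographs
(occlusal, apical, buccal, lingual, mesial, distal), and usable for any
task where one label must be predicted from a fixed set of view-tagged
images of the same object.

## Who this is for

Researchers in dental education, forensic odontology and biological image
analysis who need to (a) classify specimens from multi-view photograph
sets, (b) turn multiple imperfect rater annotations into defensible
reference labels, and (c) evaluate classifiers honestly when the fine
label itself is uncertain.

## What is inside

**The model.** A shared-weight convolutional encoder maps each of the six
views to a feature token; a transformer-style attention encoder fuses the
tokens (a learned aggregation token pools them) and a softmax head yields
class probabilities

```
p(c | x_1..x_6) = softmax(W · AttnEncoder(cls, f(x_1)+e_1, ..., f(x_6)+e_6))_c
```

with one encoder `f` shared across views and learned view-identity
embeddings `e_v`. Images are letterboxed (aspect-ratio-preserving resize
plus black padding) to the square model input. Training uses Adam
(β₁ = 0.9, β₂ = 0.99), weight decay on weight matrices only,
label-smoothed cross-entropy (ε = 0.1), a linear-warmup + poly(1.5)
learning-rate schedule, and stochastic rotation / cutout / perspective /
affine augmentation with probabilities 0.5 / 0.2 / 0.2 / 0.2. All
forward and backward passes are implemented in R and verified against
numeric gradients.

**Consensus refinement.** Four annotations per specimen vote with
weights (2, 2, 1, 1); a specimen receives a pseudo-ground-truth (P-GT)
label only when a category scores ≥ 4, and is removed as ambiguous
otherwise. Equivalently: the two reliable raters agree, or one of them
agrees with both others — an equivalence the test suite verifies by
exhausting all 16⁴ vote assignments.

**Hierarchical evaluation.** Top-k accuracy (rank of the true class),
confusion matrices, per-class and macro sensitivity/specificity
(`TP/(TP+FN)`, `TN/(TN+FP)`), one-vs-rest ROC/AUC, Cohen's κ (model vs
P-GT) and Fleiss' κ (among raters) — each at 16-class, 6-class
(jaw × tooth type) and 3-class (tooth type) granularity, by merging the
fine model's outputs.

**Synthetic data.** A procedural renderer draws tooth-like specimens
whose class-determining attributes are split across views (cusp count
visible only from above, root count only from the side), including a
designed class pair that is indistinguishable from any single view yet
fully determined by the set; plus simulated annotators with
adjacency/counterpart-structured confusion.

## Worked example

```r
library(toothset)

# Aggregate a 16-class specimen count table to coarser granularities
dist <- read.csv(system.file("extdata", "class_distribution.csv",
                             package = "toothset"))
counts <- setNames(dist$count, dist$class)
regroup_counts(counts, "6-type")
#>  UA  UP  UM  LA  LP  LM
#> 157 104 163 160 109 157
regroup_counts(counts, "3-type")
#>   A   P   M
#> 317 213 320

# Weighted-vote consensus
score_categories(c(A0 = "U3", A1 = "U3", A2 = "L3", A3 = "L3"))
#> U3 L3
#>  4  2
refine(list(
  s1 = c(A0 = "U3", A1 = "U3", A2 = "U1", A3 = "L3"),  # accepted: U3
  s2 = c(A0 = "U3", A1 = "L3", A2 = "L3", A3 = "L3"),  # accepted: L3
  s3 = c(A0 = "U3", A1 = "L3", A2 = "U4", A3 = "U5")   # removed
))
#> <refinement_result> 3 specimens: 2 kept, 1 removed (threshold 4)

# Simulate a 200-specimen raw test set with four noisy raters, refine it,
# and measure agreement before and after refinement
truth <- withr::with_seed(1, sample(tooth_taxonomy()$fine_classes, 200, TRUE))
ann <- simulate_annotators(truth, default_rater_models(), seed = 2)
ref <- refine(ann)
ref
#> <refinement_result> 200 specimens: 172 kept, 28 removed (threshold 4)
kept <- ref$outcomes$specimen_id[ref$outcomes$outcome == "accepted"]
agreement_by_granularity(ann, n_boot = 200, seed = 3)
#>   granularity fleiss_kappa  ci_lower  ci_upper n_subjects
#> 1     16-type    0.5944294 0.5412435 0.6381514        200
#> 2      6-type    0.7476187 0.6961634 0.7855715        200
#> 3      3-type    0.8882267 0.8518829 0.9216026        200
agreement_by_granularity(ann, specimen_ids = kept, n_boot = 200, seed = 3)
#>   granularity fleiss_kappa  ci_lower  ci_upper n_subjects
#> 1     16-type    0.6681829 0.6266192 0.7102202        172
#> 2      6-type    0.8112425 0.7634827 0.8487974        172
#> 3      3-type    0.9177143 0.8764389 0.9519866        172
```

Reading the numbers: agreement among simulated raters is moderate at the
16-class level and rises as classes merge (most disagreement sits between
adjacent positions and across jaws), and the voting filter removes
exactly the specimens on which no weighted majority exists, which lifts
Fleiss' κ at every granularity — the qualitative signature the consensus
procedure is designed to produce.

To train and evaluate a classifier end to end on synthetic data:

```r
bench <- run_separable_benchmark(seed = 1, with_baseline = TRUE)
bench$top1               # set-model test accuracy (e.g. 0.975)
bench$pair_top1          # accuracy on the view-complementary pair
bench$baseline_pair_top1 # occlusal-only baseline on the same pair (~0.5-0.6)
```

The benchmark trains the tiny set classifier for ten epochs on a
4-class preset (200 train / 80 test specimens) in which one class pair
can only be separated by combining top-down and side views, then trains a
single-view baseline with the identical recipe; the gap on that pair is
the direct measurement of what attention fusion adds.

## Documentation

The methods vignette (`vignettes/toothset-methods.Rmd`) documents the
model and its assumptions, the consensus rule, every tunable parameter
with its default and provenance, the synthetic generator's design and its
limits, and the package's numerical choices.
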