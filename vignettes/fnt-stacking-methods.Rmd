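---
title: "Flexible neural tree stacking for active-compound screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible neural tree stacking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Virtual screening for disease-related active compounds is a small-sample,
imbalanced binary classification problem: a few dozen literature-curated
actives against a several-fold excess of property-matched decoys, each
compound described by a vector of continuous molecular descriptors.  No
single classifier family is uniformly best on such tables — linear margins,
tree ensembles and neighbourhood methods each exploit different kinds of
descriptor structure — which motivates a stacked ensemble: nine base
classifiers each emit a positive-class confidence, and a nonlinear
meta-learner maps the confidence vector $c = (c_1, \dots, c_9)$ to a final
score.

`fntstack` implements that pipeline with a **flexible neural tree (FNT)**
as the meta-learner, alongside averaged and voting baseline ensembles and a
full cross-validated evaluation harness.

# The flexible neural tree

An FNT is a tree whose leaves are input variables and whose internal nodes
are *flexible neuron operators*.  An operator of arity $i$ with weights
$w_1..w_i$, centre $a$ and width $b$ computes

$$\mathrm{net} = \sum_{j=1}^{i} w_j\,x_j, \qquad
  o = \exp\!\left(-\left(\frac{\mathrm{net} - a}{b}\right)^{2}\right),$$

so every operator output lies in $(0, 1]$.  The tree is cross-layer: a
variable may appear at any depth, repeatedly or not at all, so the tree
performs implicit input selection.  We require the root to be an operator
node so the model output is always a probability-like score, classified at
a 0.5 threshold.  The operator set is $+_2..+_5$ (arities 2–5) and the
variable set is $c_1..c_9$, the nine base-learner confidences in a fixed,
documented order: gcforest, svm, rf, adaboost, dtree, gbdt, knn, logreg,
nbayes.

Numerical guards: evaluation divides by $b$, so widths with
$|b| < 10^{-6}$ are rejected as degenerate; mutation and annealing clamp
$|b| \ge 10^{-3}$ away from that floor.

# Training the tree: structure search plus annealing

Structure and parameters are learned by a hybrid evolutionary method
(`fnt_evolve()`):

* **Structure** — generational genetic programming: tournament selection
  (size 3, ties broken towards smaller trees), subtree crossover (depth
  violations repaired by truncating too-deep subtrees to random leaves),
  and four equiprobable mutation kinds (fresh random subtree, leaf
  reindexing, operator arity change with padding/truncation, Gaussian
  parameter jitter).  The champion survives each generation unchanged, so
  best fitness is monotonically non-increasing.
* **Parameters** — simulated annealing (`fnt_anneal()`) on the champion:
  one uniformly chosen parameter is perturbed per proposal with standard
  deviation `sa_step_scale * temperature`; deteriorations are accepted
  with probability $\exp(-\Delta/T)$ under geometric cooling.  The best
  tree seen is returned, so annealing never worsens fitness.  Because the
  structure is frozen during annealing, the tree is flattened into
  post-order arrays and each proposal re-evaluates only the perturbed
  node's ancestor chain, which keeps the $\sim$2,700-proposal schedule
  affordable in plain R.
* Annealing runs on a generation's champion only when the champion has
  changed since the last annealing call: re-annealing an unchanged,
  already-annealed elite with the same schedule costs roughly a hundred
  times the genetic-programming budget per generation and has no expected
  benefit.

The fitness is the root-mean-square error between tree output and the 0/1
labels plus a parsimony penalty of $10^{-3}$ per node.  Defaults:
population 50, generations 100, max depth 4, crossover 0.8, mutation 0.3;
annealing $T_0 = 1$, cooling 0.95, 20 proposals per temperature, stop at
$10^{-3}$, step scale 0.5.  All are overridable through `fnt_control()`
and every run is exactly reproducible from its seed.

The initial population is *seeded*: it contains, for every input $c_j$,
one monotone single-operator tree ($\mathrm{net} = c_j$, centre 1, width
0.6 — increasing on $(0,1]$ and crossing 0.5 at $c_j = 0.5$), so the
search starts from each base learner's own ranking and evolution can only
improve on the best of them in training fitness.  The remaining
individuals are random grow-method trees whose children become leaves with
probability $\sqrt{d/d_{\max}}$ at depth $d$ (leaf-heavy initialisation;
parsimony pressure keeps later generations small).

# The nine base classifiers

The base learners are used with their library defaults: SVM and naive
Bayes from `e1071` (SVM confidences via the built-in Platt calibration of
the margin), random forest from `ranger`, the decision tree from `rpart`,
gradient boosting from `xgboost` (100 rounds, logistic objective), KNN
from `class` (k = 5, vote-fraction confidence), logistic regression from
`stats::glm`, and two components implemented in this package: AdaBoost
(SAMME over depth-1 `rpart` stumps, 50 rounds; confidence is the
alpha-weighted mean of stump leaf class-1 proportions, which stays near
the class prior on signal-free data) and the multi-grained cascade forest
below.

**Stacking protocol.**  The meta-learner must not be trained on
resubstitution confidences: a base learner that overfits emits
near-perfect in-sample confidences, and the meta-learner would learn to
trust it blindly.  `confidence_matrix()` therefore scores every training
compound *out-of-fold* (stratified 5-fold by default): row $i$'s
confidences come from models whose training folds excluded row $i$.  A
`protocol = "resub"` escape hatch mimics the naive reading.  Fold
assignment is keyed to row identifiers, so permuting the rows of a table
does not change any row's fold.  For deployment the nine learners are
refit on the full training set (standard stacking).

# The multi-grained cascade forest

`gcforest_fit()` composes two stages.  *Multi-grained scanning*: each
window of size $k$ slides over the $m$ descriptors producing
$s = (m-k)+1$ contiguous sub-vectors per compound; a completely-random
forest (each split on one uniformly random feature at a random threshold,
grown to purity — realised as an extremely-randomised `ranger` forest with
`mtry = 1`, one random split per feature, minimum node size 1) and a
Gini random forest score every sub-vector with a 2-class probability
vector, giving $4s$ representation values per window; windows are
concatenated.  *Cascade*: layers of one completely-random and one random
forest; layer $t \ge 2$ sees the scanned representation plus layer
$t-1$'s four class-vector values; growth stops when 3-fold internal
accuracy fails to improve (patience 1) or at 10 layers, and prediction
averages the final layer's two class vectors, breaking ties towards the
positive class.

Choices the description leaves open, fixed here: scanning probabilities
for training data are produced out-of-fold (3-fold, sub-instances of a
compound share its fold) to limit representation leakage; the cascade input
is the scanned representation only; default windows are
$\lceil m/4 \rceil$ and $\lceil m/2 \rceil$.  The phrase "$2s_1$
representation vectors" is read as dimension ($2$ forests $\times s$
sub-vectors $\times 2$ probabilities $= 4s$ values per window), the usual
deep-forest convention.  Two efficiency defaults: scanning forests use 20
trees (cascade forests keep 100 — scanning emits $2s$ highly redundant
probability pairs per forest, so large scanning forests add little), and
the pooled $n \times s$ sub-instance table is subsampled to at most 1,500
rows for scanning-forest training (a standard deep-forest practice; all
sub-instances are still scored).

# Evaluation harness

`confusion()`, `classification_metrics()` (TPR, FPR, Precision,
Specificity, F1; Precision is defined as 1 when no positive predictions
are made and F1 as 0 when precision and TPR are both 0),
`roc_auc()` (threshold sweep over unique scores; the trapezoidal area
equals the Mann–Whitney rank statistic with ties counted ½, a property the
test suite verifies against an independent pairwise oracle), and
`cross_validate()` / `compare_methods()` for stratified k-fold protocols
with $k \in \{2, 4, 6, 8, 10, 15\}$.  Metrics are pooled over folds
(summed confusions; concatenated out-of-fold scores for the ROC) rather
than averaged: pooled values are compatible with integer-ratio metric
tables and give one value per $k$.  Stratification is essential at 1:3
imbalance and $k = 15$.  The voting baseline scores a compound by its
fraction of positive votes, so thresholding at 0.5 is exactly the
majority vote (nine voters, no ties); the averaged baseline is the
arithmetic mean of the nine confidences.

# The synthetic benchmark

The original screening dataset (88 literature-curated actives, 264
DUD·E-style decoys) is not deposited, so `generate_dataset()` emulates its
shape: 88/264 by default, 50 continuous descriptors, fully determined by
a seed.  Three structures:

* `blobs` — a mean shift of fixed absolute size 2 on a random fifth of
  the descriptors; with `noise_sd = 0.5` this gives well-separated
  classes (used as an easy end-to-end toy), with `noise_sd = 1` a
  moderate problem.
* `complementary` — the stacking benchmark.  Three blocks aim at
  different learner families: six *masked linear-contrast pairs* (a
  latent factor of sd 2 dominates both features of a pair; the class
  signal of 0.5 lives in their difference, recoverable by any linear
  margin but nearly invisible to axis-additive splits and marginal
  models at this sample size), three *XOR sign-pairs* (±0.85 same-sign
  offsets for actives, opposite-sign for decoys: zero marginal shift, so
  linear models are blind while depth-2 axis splits recover it), and
  eight *oblique local-cluster* features (four active and four decoy
  cluster centres, then a random rotation: neighbourhood methods see the
  clusters through rotation-invariant distances, axis-aligned splits see
  them poorly).  Remaining descriptors are pure noise.  Under this
  design single-learner test AUCs spread over roughly 0.60–0.85 with
  different winners on different seeds.
* `null` — labels independent of all features; the leakage canary.  Any
  learner or ensemble with held-out AUC away from 0.5 on this structure
  indicates an evaluation bug.

What the generator does *not* emulate: real descriptor marginals
(log-normal, integer counts, collinear physicochemical families),
activity cliffs, and decoy selection bias.  Passing tests on this
benchmark therefore demonstrate correctness of the pipeline and the
qualitative complementarity mechanism, not screening performance on real
chemistry.

# Problem sizes and stochastic suites

The test suite runs its stochastic acceptance checks at the study's own
scale: evolution sanity over 20 seeds ($n = 300$), the stacking
comparison over 20 seeds of the full 88/264 benchmark (stratified 75/25
holdout), and the leakage canary over 10 seeds with pooled held-out
scores (concatenating the ten test halves before computing each method's
AUC, which tightens the chance-level interval compared with per-seed
AUCs).  The acceptance script reports pooled 4-fold cross-validated
metrics on one seed of the default benchmark.

# Known limitations

* On the complementary benchmark the FNT stacker beats or ties the *best*
  of the nine single learners in roughly half the seeds rather than
  consistently.  The achievable margin is structurally small at this
  sample size: even an oracle meta-learner fitted on the test confidences
  themselves gains only 0.03–0.05 AUC over the maximum of nine
  correlated single-learner AUCs, while that maximum carries a selection
  bias of similar size at an 88-compound test set, and the out-of-fold to
  deployed-model transfer costs a further ~0.03.  The stacker's honest
  position is "matches the best single learner without knowing which one
  it is", which is itself the practically useful property.
* The RMSE loss with a 0.5 threshold is conservative under 1:3 imbalance:
  pooled TPR of the stacker is modest while its ranking (AUC) is strong.
  Users screening for candidates should rank by confidence rather than
  use the hard labels.
* gcForest's sliding windows presuppose meaningful descriptor ordering;
  on unordered descriptor tables (as here) scanning can dilute block
  structure, and gcForest is accordingly not the strongest base learner
  on this benchmark.
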