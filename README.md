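# fntstack

Nonlinear stacked ensembles for virtual-screening classification, with a
**flexible neural tree (FNT)** meta-learner.

## The problem and the model

Screening for disease-related active compounds is typically a small,
imbalanced binary problem: tens of curated actives against a several-fold
excess of decoys, each compound a vector of molecular descriptors.  Nine
base classifiers — a multi-grained cascade forest (gcForest), SVM, random
forest, AdaBoost, decision tree, gradient-boosted trees, KNN, logistic
regression and naive Bayes — each emit a positive-class confidence
`c = (c1, ..., c9)`.  A flexible neural tree maps that confidence vector
to the final score: a tree whose leaves are the `cj` and whose internal
nodes are Gaussian neuron operators

    net = sum_j w_j x_j,      o = exp(-((net - a) / b)^2)  in (0, 1],

so the tree is a sparse, cross-layer nonlinear combiner.  Its structure is
found by genetic-programming search (tournament selection, subtree
crossover, four mutation kinds, elitism) and its parameters `(w, a, b)`
are refined by simulated annealing.  Averaged and majority-voting
ensembles are included as baselines, along with a confusion/ROC/AUC
harness with stratified k-fold protocols (k = 2, 4, 6, 8, 10, 15) and a
synthetic benchmark generator that emulates an 88-active / 264-decoy
descriptor table with block-structured signal, so that linear, tree and
neighbourhood learners are differentially informative.

Base learners are delegated to `e1071`, `ranger`, `rpart`, `xgboost`,
`class` and `stats`; the FNT, its evolutionary trainer, the cascade
forest, AdaBoost and the evaluation harness are implemented here.

## Worked example

```r
library(fntstack)

d <- generate_dataset(dataset_spec(seed = 1))   # 88 actives, 264 decoys
d
#> Labelled descriptor table: 352 compounds x 50 descriptors (88 active, 264 decoy; structure 'complementary')

set.seed(1)
fold <- sample(rep(1:4, length.out = 352))      # keep a held-out quarter
fit <- fnt_stack(d$features[fold != 1, ], d$label[fold != 1],
                 evolution = fnt_control(seed = 1))
fit
#> Flexible-neural-tree stacking ensemble
#>   base learners: gcforest, svm, rf, adaboost, dtree, gbdt, knn, logreg, nbayes
#>   stacking: oof (k_inner = 5), threshold 0.5
#>   meta-learner: (+2 w=0.2510441221040855,0.53417292775033676 a=0.83838512898485906 b=0.53703006771108308 (c8) (c6))

conf <- predict(fit, d$features[fold == 1, ])   # confidences in (0, 1]
roc_auc(d$label[fold == 1], conf)$auc
#> [1] 0.7923177
```

The printed meta-learner is the tree's s-expression: here evolution kept a
single operator reading `c8` (logistic regression) and `c6` (gradient-boosted trees) — the
tree performs input selection among the nine learners.  `compare_methods()`
runs the full cross-validated comparison of the stacker, all nine single
learners and both baselines under shared folds, and
`classification_metrics()` / `roc_auc()` reproduce the usual TPR / FPR /
Precision / Specificity / F1 / AUC reporting.

A thin command-line interface (`inst/cli/fntstack.R`) exposes the same
pipeline as `simulate`, `train`, `predict`, `evaluate` and `compare`
subcommands.

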