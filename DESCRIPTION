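Package: fntstack
Title: Flexible Neural Tree Stacking Ensembles for Active-Compound Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear stacked-generalization ensembles for binary
    virtual-screening classification (actives versus decoys).  Nine base
    classifiers, including a multi-grained cascade forest (gcForest),
    emit positive-class confidences that feed a flexible neural tree
    (FNT) meta-learner: a tree of Gaussian neuron operators whose
    structure is found by genetic-programming search and whose
    parameters are refined by simulated annealing.  Includes averaged
    and voting baseline ensembles, a confusion/ROC/AUC evaluation
    harness with stratified k-fold cross-validation, and a synthetic
    benchmark generator emulating imbalanced active/decoy descriptor
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    ranger,
    rpart,
    e1071,
    xgboost,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
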