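Package: motionseq
Title: Sequence-Based Assessment and Recognition of Skeletal Exercise Motions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for grading and recognising skeletal motion-capture
    recordings of fixed exercise routines against teacher references. Reads
    and writes BVH (Biovision Hierarchy) motion files, converts Euler-angle
    channels to quaternions, computes global joint positions by forward
    kinematics, extracts keyframes at a preset compression rate by k-means
    clustering of pose coordinates, and compares motions with per-joint
    windowed dynamic time warping. Distance features feed a suite of
    classifiers (k-NN, SVM, naive Bayes, logistic regression, decision tree,
    back-propagation and radial-basis-function networks); discrete-emission
    hidden Markov models and minimal LSTM/BiLSTM/GRU networks classify the
    keyframe sequences directly. Includes a synthetic labelled motion-cohort
    generator, stratified cross-validated evaluation with confusion matrices,
    Kendall tau-b rater concordance and chi-square method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    e1071,
    rpart,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
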