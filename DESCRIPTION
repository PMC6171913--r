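Package: KronDTI
Title: Multi-Task Kronecker Kernel SVM for Drug-Target Interaction Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemogenomic prediction of protein-ligand interactions with
    multi-task support vector machines in (protein, molecule) pair space.
    Provides molecular graph kernels (Tanimoto path kernel, marginalized
    random-walk kernel), protein sequence kernels (Smith-Waterman score
    kernel with positive-semidefinite repair, local-alignment kernel,
    substitution-neighborhood k-mer kernel, family-hierarchy kernel), a
    factorized Kronecker pair-kernel SVM with single-task baselines,
    reduced per-query training-set construction (intra-task pairs,
    nearest-neighbor or random extra-task pairs, controlled negative
    sampling, percentile similarity filters), weighted-nearest-neighbor
    de-orphanization, orphan-aware cross-validation schemes (random,
    orphan-ligand, orphan-protein, double-orphan, clustered variants,
    leave-one-out, nested), ranking metrics (ROC-AUC, AUPR), degree-balanced
    negative test-set generation, and a synthetic planted-cluster dataset
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    kernlab,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
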