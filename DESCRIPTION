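Package: acpaug
Title: Anticancer Peptide Prediction with Feature-Space Data Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies peptides as anticancer (ACP) or non-ACP from sequence
    alone. Peptides are length-normalized by X-padding, encoded as a
    concatenation of N-terminal binary profile features, per-position AAindex
    physicochemical descriptors (reduced to the 50 most informative columns by
    minimum-redundancy maximum-relevance selection), and optionally a
    reduced-alphabet k-mer sparse matrix compressed by singular value
    decomposition. Training folds are enlarged by noise-adding oversampling in
    feature space (masked multiplicative perturbation of the AAindex block),
    and classifiers (a 6x100 multilayer perceptron by default) are scored by
    stratified five-fold cross-validation with accuracy, precision,
    sensitivity, specificity and the Matthews correlation coefficient.
    Includes a synthetic peptide generator with a tunable N-terminal
    compositional signal for end-to-end testing, plus parameter-sweep,
    feature-ablation and classifier-comparison drivers and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    e1071,
    jsonlite,
    randomForest,
    ranger,
    rpart,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
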