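Package: diffpat
Title: Differential Pattern Analysis of Time-Course Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests for differential temporal expression patterns between
    treatments in time-course RNA-seq experiments. Expression profiles are
    encoded as module-membership (kME) correlations against co-expression
    module eigengenes, compared with empirical-Bayes moderated linear-model
    contrasts, and assigned empirical p-values from permutation nulls.
    Includes paralog-pair divergence testing with orientation, permutation
    enrichment tests for condition-responsive genes, tree-ensemble gene
    regulatory network inference with permuted-network FDR thresholding,
    cross-species target-overlap divergence tests, conserved noncoding
    sequence (CNS) to gene association utilities, harmonic-regression
    rhythm detection, and seeded synthetic-data generators with known
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    edgeR,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
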