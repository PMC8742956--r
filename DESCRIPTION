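Package: ocmod
Title: Overlapping Co-Expressed Gene Module Detection by Matrix Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects overlapping co-expressed gene modules from a bulk or
    single-cell gene-expression matrix using independent component analysis
    (FastICA with the logcosh negentropy contrast) or independent principal
    component analysis (IPCA). The number of components is chosen by a
    permutation-based parallel analysis, non-Gaussian signatures are retained
    by a kurtosis filter, and genes are assigned to modules either by a
    tail-area false-discovery-rate fitted to a median-centred Gaussian null
    or by a z-score cut-off, so that one gene may belong to several modules.
    Includes hub-gene ranking, module-trait Pearson association, eigengene
    comparison utilities for benchmarking against hard clusterings, and a
    seeded synthetic-data generator with planted overlapping modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
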