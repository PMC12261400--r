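Package: hideconv
Title: Hierarchical Cell-Type Deconvolution of Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reference-based cell-type deconvolution that walks a
    user-supplied cell-type hierarchy from major populations down to the
    finest subtypes. At every node of the tree, per-gene weights are learned
    by loss-function learning (maximizing the Pearson correlation between
    estimated and known proportions on training mixtures), proportions are
    estimated by weighted non-negative least squares, and child estimates
    are constrained to sum exactly to their parent's estimate, yielding
    consistent multi-resolution cellular proportions. Includes a
    hierarchical single-cell simulator and pseudo-bulk generator for
    training and validation, consensus reference building with
    high-variance gene selection, cross-platform gene-wise bulk rescaling,
    and benchmarking metrics (per-type Pearson correlation, normalized mean
    absolute error, cross-level consistency).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Matrix,
    data.table,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
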