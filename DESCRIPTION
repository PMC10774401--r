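Package: chronoDEG
Title: Time-of-Day Differential Expression Analysis for NanoString
    nCounter Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing NanoString nCounter count data sampled at
    different times of day. Implements the nSolver-style normalization chain
    (negative background subtraction, positive-control normalization, CodeSet
    content normalization by geometric means, then quantile normalization on
    log2 values), per-gene tumor-versus-control t-tests with p-value,
    fold-change standard-deviation, and combined DEG filters, pooling of
    per-region DEG lists into whole-brain unique lists, dark/light overlap
    statistics, immune cell-type marker summaries, hypergeometric gene-set
    over-representation, tumor endpoint statistics, and a negative-binomial
    simulator of the full study design with planted phase-specific
    differentially expressed genes for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
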