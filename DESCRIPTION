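Package: kirbind
Title: Sequence-Based Prediction of KIR3DL1 Binding to HLA Class I Allotypes
Version: 0.1.0
Authors@R:
    person("kirbind", "maintainers", email = "kirbind@example.org", role = c("aut", "cre"))
Description: Tools to model the interaction between the polymorphic natural
    killer cell receptor KIR3DL1 and HLA class I allotypes from amino-acid
    sequence alone. Aligned alpha1/alpha2 domain sequences are one-hot
    encoded over structurally motivated region masks (full domain, Bw4
    motif, helices, loop-free), projected to low dimension by PCA or
    multiple correspondence analysis, and classified with linear support
    vector machines or a joint binary/continuous multi-label vector
    optimization (MLVO). Includes replicate aggregation and normalization
    of bead-based binding matrices, average-linkage clustering into
    high/low/non-binder classes, two-sample logo enrichment statistics,
    allele-frequency population coverage, allele-level cross-validation,
    and a deployable multi-model prediction bundle with beta-matrix export.
    A synthetic-data module generates planted log-linear binding panels so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
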