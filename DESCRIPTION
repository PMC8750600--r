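Package: pcmods
Title: Consensus Co-Expression Modules and Causal Discovery for Paired Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proteogenomic network inference on matched
    transcript and protein abundance matrices. Implements expression
    filtering for paired omics layers, weighted co-expression network
    construction with soft thresholding and topological overlap,
    consensus module detection across the two layers, module eigengene
    networks with cross-layer preservation measures, and estimation of
    the completed partially directed acyclic graph (CPDAG) among module
    eigengenes with the PC algorithm using Fisher-z conditional
    independence tests. Ships a linear Gaussian structural equation
    model simulator that plants known modules and a known causal DAG
    so that every stage of the pipeline can be validated against
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
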