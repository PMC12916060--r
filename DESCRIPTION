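Package: visnetr
Title: Trace-Learning Competitive Hierarchies for Invariant Object Recognition
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rate-based simulation of the VisNet family of models of the
    ventral visual cortical stream: a four-layer feedforward competitive
    network with Gabor-filtered V1-like input, diluted Gaussian retinotopic
    connectivity, sparseness-controlled sigmoid activation, and short-term
    memory trace learning that builds transform-invariant object
    representations from temporally contiguous views. Implements three
    synaptic update rules (Hebbian learning with explicit weight-vector
    normalisation, the standard competitive rule with weight-dependent
    heterosynaptic depression, and the Oja rule), optional synaptic weight
    clipping, a synthetic multi-view stimulus generator, the layer-4
    object-selectivity statistic, replicate and capacity analyses, and
    weight-distribution diagnostics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    yaml,
    jsonlite,
    fitdistrplus,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
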