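Package: fcnet
Title: Wavelet Functional Connectomes and Small-World Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds task-fMRI functional connectivity networks from ROI
    time-series via maximum-overlap discrete wavelet transform (MODWT)
    band coefficients, characterizes their small-world topology
    (global, local and nodal efficiency against degree-matched regular
    and random null models, hub detection by one-sided z-test,
    exponentially truncated power-law degree fits), detects
    group-different subnetworks with the permutation-based
    network-based statistic (NBS), and relates nodal metrics to
    clinical scores with covariate-adjusted linear models and FDR
    correction.  Includes frame-wise head-motion quality control and a
    synthetic two-group cohort generator with planted connectivity
    effects so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
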