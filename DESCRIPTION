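Package: adaptscales
Title: Spectral Mutual-Information Profiling of Cellular Adaptation Hierarchies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping where environmental information lives in the
    eigenspectrum of single-cell expression ensembles. Implements quality
    control and log-normalization of UMI count matrices, SVD/PCA eigenspectrum
    analysis with variance-explained fractions and gene loadings, windowed
    spectral-correlation mutual-information profiling of categorical
    environmental cues (SCALES) with permutation nulls and hierarchy ranking by
    spectral depth, dual-stress transcriptional epistasis scoring against a
    log-additive independence expectation, and physiological quantifications
    (polysome-to-monosome ratios from A260 traces, maximum growth rates from OD
    curves, competitive-fitness selection coefficients from flow-cytometry
    count series). A synthetic-data module generates multi-condition ensembles
    with cue signals planted at chosen spectral depths, bulk dual-stress
    designs with controlled epistasis, absorbance traces, growth curves and
    competition series, with full ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5,
    optparse
Config/testthat/edition: 3
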