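Package: drgquant
Title: Quantification of DRG Calcium Imaging, Marker Co-Expression and
    Behavioral Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stimulus-locked quantification of in vivo dorsal root ganglion
    (DRG) calcium imaging (delta-F/F0 normalization, 4-SD responder calling,
    peak area under the curve, density-extrapolated neuron totals, responder
    size distributions), per-cell marker co-expression analysis (RNAscope-style
    combination counting with nested section/animal aggregation and diameter
    distributions; single-cell count-matrix QC filtering, log-normalization
    and threshold co-expression), and behavioral and molecular endpoint
    derivations (swelling difference scores, time-course AUC, log-transformed
    withdrawal thresholds, comparative delta-delta-CT). A synthetic-data
    generator emulates the acquisition protocols with full ground truth so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    pracma,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'utils.R'
    'protocol.R'
    'session.R'
    'markers.R'
    'imaging.R'
    'summary.R'
    'synth-imaging.R'
    'synth-markers.R'
    'synth-counts.R'
    'synth-timecourse.R'
    'coexpr-markers.R'
    'coexpr-counts.R'
    'endpoints.R'
    'io.R'
    'drgquant-package.R'
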