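#' Framed fluorescence recording with protocol metadata
#'
#' `ImagingSession` holds one recording as a neurons x frames fluorescence
#' matrix (arbitrary units) in the `"fluorescence"` assay of a
#' [SummarizedExperiment::SummarizedExperiment], with per-neuron soma areas
#' (µm²) in `rowData` and the [ImagingProtocol-class] in `metadata`.
#'
#' @param traces Numeric matrix, neurons x frames; row names are neuron ids
#'   (defaults to `n1..nN`).
#' @param protocol An [ImagingProtocol-class]; the trace length must equal
#'   [totalFrames()] of the protocol.
#' @param areas Per-neuron soma areas in µm².
#' @param x An `ImagingSession`.
#'
#' @return `ImagingSession()` returns an `ImagingSession` object; `traces()`
#'   the fluorescence matrix; `neuronAreas()` the area vector;
#'   `imagingProtocol()` the protocol.
#' @examples
#' p <- ImagingProtocol(stimulusLabels = "30g")
#' f <- matrix(100, nrow = 2, ncol = totalFrames(p))
#' s <- ImagingSession(f, p, areas = c(350, 600))
#' neuronAreas(s)
#' @aliases ImagingSession traces neuronAreas
#' @export ImagingSession
#' @exportClass ImagingSession
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame metadata
setClass("ImagingSession", contains = "SummarizedExperiment")

setValidity("ImagingSession", function(object) {
  msg <- character()
  if (!"fluorescence" %in% assayNames(object))
    msg <- c(msg, "assay 'fluorescence' is required")
  p <- metadata(object)$protocol
  if (!is(p, "ImagingProtocol")) {
    msg <- c(msg, "metadata$protocol must be an ImagingProtocol")
  } else if ("fluorescence" %in% assayNames(object) &&
             ncol(object) != totalFrames(p)) {
    msg <- c(msg, sprintf("trace length (%d) must equal protocol total frames (%d)",
                          ncol(object), totalFrames(p)))
  }
  if ("fluorescence" %in% assayNames(object)) {
    f <- assay(object, "fluorescence")
    if (any(!is.finite(f)) || any(f < 0))
      msg <- c(msg, "fluorescence must be finite and non-negative")
  }
  if (!"area_um2" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData$area_um2 is required")
  else if (any(rowData(object)$area_um2 <= 0))
    msg <- c(msg, "all neuron areas must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname ImagingSession-class
ImagingSession <- function(traces, protocol, areas) {
  traces <- as.matrix(traces)
  if (is.null(rownames(traces)))
    rownames(traces) <- paste0("n", seq_len(nrow(traces)))
  se <- SummarizedExperiment(
    assays = list(fluorescence = traces),
    rowData = DataFrame(area_um2 = as.numeric(areas), row.names = rownames(traces)),
    metadata = list(protocol = protocol))
  new("ImagingSession", se)
}

#' @rdname ImagingSession-class
#' @export
setMethod("traces", "ImagingSession", function(x) assay(x, "fluorescence"))

#' @rdname ImagingSession-class
#' @export
setMethod("neuronAreas", "ImagingSession",
          function(x) setNames(rowData(x)$area_um2, rownames(x)))

#' @rdname protocol-accessors
#' @export
setMethod("imagingProtocol", "ImagingSession",
          function(x) metadata(x)$protocol)

setMethod("show", "ImagingSession", function(object) {
  p <- metadata(object)$protocol
  cat(sprintf("ImagingSession: %d neurons x %d frames (%g Hz, %d stimuli: %s)\n",
              nrow(object), ncol(object), p@frameRate,
              length(p@stimulusLabels),
              paste(p@stimulusLabels, collapse = ", ")))
})

#' Normalized traces: per-neuron ΔF/F₀ with baseline statistics
#'
#' Produced by [computeDff()]; carries the `"dff"` assay (dimensionless
#' ΔF/F₀ per frame), per-neuron `f0` (mean baseline fluorescence) and
#' `baseline_sd` (SD of ΔF/F₀ over the designated baseline period) in
#' `rowData`, soma areas, and the protocol in `metadata`.
#'
#' @param x A `DffTraces` object.
#' @return `dff()` returns the ΔF/F₀ matrix; `baselineF0()` and
#'   `baselineSD()` the per-neuron statistics.
#' @aliases DffTraces dff baselineF0 baselineSD
#' @name DffTraces-class
#' @exportClass DffTraces
setClass("DffTraces", contains = "SummarizedExperiment")

setValidity("DffTraces", function(object) {
  msg <- character()
  if (!"dff" %in% assayNames(object))
    msg <- c(msg, "assay 'dff' is required")
  need <- c("f0", "baseline_sd", "area_um2")
  miss <- setdiff(need, colnames(rowData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing rowData columns:", paste(miss, collapse = ", ")))
  if ("f0" %in% colnames(rowData(object)) && any(rowData(object)$f0 <= 0))
    msg <- c(msg, "f0 must be positive")
  if (!is(metadata(object)$protocol, "ImagingProtocol"))
    msg <- c(msg, "metadata$protocol must be an ImagingProtocol")
  if (length(msg)) msg else TRUE
})

#' @rdname DffTraces-class
#' @export
dff <- function(x) {
  stopifnot(is(x, "DffTraces"))
  assay(x, "dff")
}

#' @rdname DffTraces-class
#' @export
baselineF0 <- function(x) {
  stopifnot(is(x, "DffTraces"))
  setNames(rowData(x)$f0, rownames(x))
}

#' @rdname DffTraces-class
#' @export
baselineSD <- function(x) {
  stopifnot(is(x, "DffTraces"))
  setNames(rowData(x)$baseline_sd, rownames(x))
}

#' @rdname ImagingSession-class
#' @export
setMethod("neuronAreas", "DffTraces",
          function(x) setNames(rowData(x)$area_um2, rownames(x)))

#' @rdname protocol-accessors
#' @export
setMethod("imagingProtocol", "DffTraces",
          function(x) metadata(x)$protocol)

setMethod("show", "DffTraces", function(object) {
  cat(sprintf("DffTraces: %d neurons x %d frames (baseline mode '%s', %s SD)\n",
              nrow(object), ncol(object),
              metadata(object)$baselineMode %||% "global",
              metadata(object)$sdType %||% "sample"))
})

#' Per-stimulus session summary
#'
#' Produced by [summarizeSession()]. Holds, per stimulus, the responder
#' count, the (possibly density-extrapolated) total number of neurons
#' imaged, percent responders and the mean peak AUC over responders, plus
#' per-stimulus relative frequency distributions of responder soma areas.
#'
#' @param object A `SessionSummary`.
#' @return `stimulusSummary()` returns the per-stimulus data frame;
#'   `areaDistribution()` the long histogram data frame (stimulus, bin
#'   bounds, count, relative frequency).
#' @aliases SessionSummary stimulusSummary areaDistribution
#' @name SessionSummary-class
#' @exportClass SessionSummary
setClass("SessionSummary",
  representation(stimulusSummary = "data.frame",
                 areaDistribution = "data.frame",
                 binEdges = "numeric"))

setValidity("SessionSummary", function(object) {
  msg <- character()
  ss <- object@stimulusSummary
  need <- c("stimulus", "n_responders", "total_neurons",
            "percent_responders", "mean_peak_auc")
  if (!all(need %in% names(ss)))
    msg <- c(msg, "stimulusSummary missing required columns")
  else if (nrow(ss) && (any(ss$percent_responders < 0) ||
                        any(ss$percent_responders > 100)))
    msg <- c(msg, "percent_responders must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' @rdname SessionSummary-class
#' @export
stimulusSummary <- function(object) {
  stopifnot(is(object, "SessionSummary"))
  object@stimulusSummary
}

#' @rdname SessionSummary-class
#' @export
areaDistribution <- function(object) {
  stopifnot(is(object, "SessionSummary"))
  object@areaDistribution
}

setMethod("show", "SessionSummary", function(object) {
  cat("SessionSummary\n")
  print(object@stimulusSummary, row.names = FALSE)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
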